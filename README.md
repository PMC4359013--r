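# relaxometry

Voxel-wise general linear relaxometry modelling of quantitative MRI maps,
for researchers working with multi-parameter mapping (MPM) protocols in
brain imaging.

Under fast exchange between water pools, the measured longitudinal
relaxation rate is a weighted sum of the rates of its contributing pools.
Using the magnetization transfer saturation map (MT, percent units) as a
surrogate for macromolecular content and the effective transverse relaxation
rate (R2*, s⁻¹) as a surrogate for iron, this becomes a linear model with
global coefficients fitted over all brain voxels of a subject:

    R1(r) = β0 + β1·MT(r) + β2·R2*(r) + ε(r)

where β0 is the relaxation rate of free water, β1·MT the macromolecular
term, β2·R2* the iron term, and ε(r) the spatially specific residual. The
coefficients are the least-squares solution of R1 = **M**β over a model
matrix **M** with columns (1, MT, R2*), built from voxels with grey/white
matter probability > 50% and CSF probability < 50%.

The package provides:

* `relax_fit()` — the model fit, returning a classed object with
  `print`/`summary`/`coef`/`predict`/`residuals`/`plot`/`simulate` methods,
  the synthesized R1 map (**M**β), Pearson correlation between synthesized
  and measured R1, and per-tissue residual summaries;
* `fit_mpm_maps()` and friends (`fit_r2star`, `estimate_r1_pd`,
  `estimate_mt_sat`, `correct_mt_b1`, `compute_mtr`) — the quantitative-map
  estimation chain from multi-echo FLASH weightings;
* `make_phantom()` / `simulate_mpm()` — a brain-like digital phantom (WM,
  cortical GM, iron-rich deep GM, CSF) and FLASH acquisition simulator with
  transmit-field inhomogeneity, so every stage is verifiable without
  scanner data;
* `run_cohort()` and `compare_model_variants()` — synthetic cohort
  summaries (coefficient stability) and model comparisons (iron-term
  ablation, MTR as an inferior surrogate);
* NIfTI-1 I/O (`load_volume`/`write_volume`) and a single-subject pipeline
  driver (`run_subject_pipeline`), plus a thin CLI in `inst/cli/`.

## Worked example

```r
library(relaxometry)

ph     <- make_phantom(default_brain_spec(seed = 42))       # 32^3, 4 classes
series <- simulate_mpm(ph, noise_sd = 0.3, seed = 42)       # PDw/T1w/MTw FLASH
maps   <- fit_mpm_maps(series, b1_rel = ph$b1_rel)          # R1, PD, MT, R2*, MTR
fit    <- relax_fit(maps$r1, maps$mt_sat, maps$r2s,
                    tissue_probs = ph$tissue_probs,
                    class_labels = ph$class_labels)
summary(fit)
```

```
General linear relaxometry model fit
  14400 voxels pooled (0 dropped)
  coefficients:
 unity     mt    r2s
0.2628 0.4044 0.0024
  Pearson r (synthesized vs measured R1): 0.9988
  residual SD: 0.0092 s^-1
  normalized residuals: -0.01 +/- 1.03 %
  per-tissue normalized residuals (%):
    gm_deep        0.05 +/- 1.07  (n = 5232)
    wm             0.08 +/- 1.01  (n = 4864)
    gm_cortical   -0.20 +/- 0.94  (n = 3944)
    csf           -0.12 +/- 1.42  (n = 360)
  implied free-water T1: 3.805 s
```

The phantom generates R1 from the linear relation with the reference
coefficients (0.2677, 0.3971, 0.0025), so the fitted values show the full
pipeline — simulation, map estimation, masking, fit — recovering the
generating model through realistic acquisition noise: coefficients within a
few percent, near-unity Pearson correlation, per-tissue residual biases well
under a percent, and an implied free-water T1 close to 1/β0 = 3.736 s.
`compare_model_variants()` on the same maps shows that dropping the iron
term inflates residuals specifically in the iron-rich deep grey matter, and
that substituting MTR for MT saturation degrades the fit and leaves
transmit-field structure in the residual map.

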