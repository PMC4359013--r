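# Shared fixtures: small phantoms and an independent Bloch-recursion oracle
# for the MT-weighted steady state.

tiny_spec <- function(seed = 1L, grid = c(16L, 16L, 16L), sd = 0.05,
                      b1_range = c(0.9, 1.1), model_beta = default_relax_beta()) {
  phantom_spec(grid_shape = grid,
               classes = default_tissue_classes_for_tests(sd),
               b1_range = b1_range, model_beta = model_beta, seed = seed)
}

default_tissue_classes_for_tests <- function(sd = 0.05) {
  list(
    tissue_class("gm_deep", r1 = 0.85, pd = 800, mt_sat = 1.2, r2s = 40,
                 within_class_sd = sd),
    tissue_class("wm", r1 = 1.1, pd = 690, mt_sat = 2.0, r2s = 21,
                 within_class_sd = sd),
    tissue_class("gm_cortical", r1 = 0.7, pd = 820, mt_sat = 1.0, r2s = 16,
                 within_class_sd = sd),
    tissue_class("csf", r1 = 0.29, pd = 1000, mt_sat = 0.05, r2s = 2,
                 within_class_sd = sd)
  )
}

# Brute-force steady state of the saturated FLASH sequence: each TR reads
# sin(a)*Mz, tips the longitudinal component by cos(a), applies the
# fractional saturation, then relaxes for TR. The per-TR contraction factor
# is (1-d)cos(a)E1 (about 0.97 at low flip), so thousands of iterations are
# needed to converge past 1e-10.
bloch_mt_steady_state <- function(pd, r1_s, flip_deg, tr_ms, mt_sat_pu,
                                  n_iter = 3000L) {
  a <- flip_deg * pi / 180
  d <- mt_sat_pu / 100
  e1 <- exp(-tr_ms / 1000 * r1_s)
  mz <- pd
  for (i in seq_len(n_iter)) {
    mz <- mz * cos(a) * (1 - d) * e1 + pd * (1 - e1)
  }
  sin(a) * mz
}

# 3D array of given constant
const_vol <- function(value, dims = c(4, 4, 4)) array(value, dims)
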