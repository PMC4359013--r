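#' Estimate R2* by log-linear regression over echoes
#'
#' Per-voxel ordinary least squares of the log signal against echo time; the
#' negative slope is R2* (converted to s^-1). With two echoes this reduces
#' exactly to the two-point form `log(S1/S2) / (TE2 - TE1)`. Voxels with any
#' non-positive echo signal are flagged invalid (`NaN`) rather than clipped,
#' which would bias the log-linear fit; downstream stages drop them.
#'
#' @param series A `"weighted_series"` with at least two echoes (typically
#'   the eight-echo PD-weighted series).
#' @return 3D array of R2* values, s^-1, with attribute `"s0"`: the signal
#'   amplitude extrapolated to TE = 0 (exponentiated intercept), used for
#'   zero-echo-time collapsing.
#' @export
fit_r2star <- function(series) {
  stopifnot(inherits(series, "weighted_series"))
  te <- series$te_ms
  if (length(te) < 2L)
    stop("R2* estimation needs at least two echoes", call. = FALSE)
  d <- dim(series$volumes)
  n <- prod(d[1:3])
  y <- matrix(series$volumes, nrow = n)          # voxels x echoes
  bad <- rowSums(y <= 0 | !is.finite(y)) > 0L
  ly <- log(pmax(y, .Machine$double.xmin))
  tc <- te - mean(te)
  slope <- as.vector(ly %*% tc) / sum(tc^2)      # per-ms slope
  icept <- rowMeans(ly) - slope * mean(te)
  r2s <- -slope * 1000                           # ms^-1 -> s^-1
  s0 <- exp(icept)
  r2s[bad] <- NaN
  s0[bad] <- NaN
  out <- array(r2s, d[1:3])
  attr(out, "s0") <- array(s0, d[1:3])
  out
}

#' Average the leading echoes of a weighted series
#'
#' Arithmetic mean over the first `n_echoes` echo volumes, the standard way
#' of boosting SNR before R1/PD/MT estimation. The mean of the used echo
#' times is recorded as the effective echo time of the averaged volume, since
#' the average retains the corresponding residual R2* weighting.
#'
#' @param series A `"weighted_series"`.
#' @param n_echoes Number of leading echoes to average (default 6).
#' @return 3D array with attribute `"effective_te_ms"`.
#' @export
average_echoes <- function(series, n_echoes = 6L) {
  stopifnot(inherits(series, "weighted_series"))
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1L)
    stop("`n_echoes` must be at least 1", call. = FALSE)
  if (n_echoes > length(series$te_ms))
    stop("`n_echoes` exceeds the number of acquired echoes", call. = FALSE)
  d <- dim(series$volumes)
  sub <- series$volumes[, , , seq_len(n_echoes), drop = FALSE]
  out <- array(rowMeans(matrix(sub, prod(d[1:3]), n_echoes)), d[1:3])
  attr(out, "effective_te_ms") <- mean(series$te_ms[seq_len(n_echoes)])
  out
}

#' Collapse a multi-echo series to a single volume
#'
#' Either averages the first `n_echoes` (the standard chain, keeping residual
#' R2* weighting at the recorded effective TE) or extrapolates the log-linear
#' echo fit of the series itself back to TE = 0 (used for validation runs
#' where the residual decay weighting must be removed).
#'
#' @param series A `"weighted_series"`.
#' @param method `"average"` or `"te0"`.
#' @param n_echoes Echoes used by `"average"`.
#' @return 3D array; for `"average"` carries `"effective_te_ms"`.
#' @export
collapse_series <- function(series, method = c("average", "te0"),
                            n_echoes = 6L) {
  method <- match.arg(method)
  if (method == "average") return(average_echoes(series, n_echoes))
  r2s <- fit_r2star(series)
  out <- attr(r2s, "s0")
  attr(out, "effective_te_ms") <- 0
  out
}

#' Estimate R1 and proton density from dual flip-angle FLASH volumes
#'
#' Rational (small-angle, short-TR) approximation of the Ernst steady state
#' applied to a low-flip PD-weighted and a high-flip T1-weighted volume:
#' \deqn{R1 = 0.5 (S_{t1} a_{t1}/TR_{t1} - S_{pd} a_{pd}/TR_{pd}) /
#'            (S_{pd}/a_{pd} - S_{t1}/a_{t1})}
#' \deqn{A = S_{pd} S_{t1} (TR_{pd} a_{t1}/a_{pd} - TR_{t1} a_{pd}/a_{t1}) /
#'           (S_{t1} TR_{pd} a_{t1} - S_{pd} TR_{t1} a_{pd})}
#' where the local flip angles `a = b1_rel * nominal` (radians) correct for
#' transmit-field inhomogeneity and TR is converted to seconds so R1 is in
#' s^-1. Passing `b1_rel = 1` yields the *apparent* (uncorrected) maps, which
#' the MT-saturation estimator deliberately consumes (see
#' [estimate_mt_sat()]).
#'
#' Voxels whose contrast denominator falls below `tol` (relative to its
#' in-volume median magnitude) are flagged `NaN`.
#'
#' @param s_pdw,s_t1w 3D volumes (averaged or TE0-collapsed echoes) of the
#'   PD- and T1-weighted acquisitions.
#' @param acq An `"mpm_acquisition"` (only `pdw` and `t1w` entries used).
#' @param b1_rel Relative B1+ map (or scalar 1).
#' @param tol Relative degeneracy tolerance for the denominator.
#' @return List with 3D arrays `r1` (s^-1) and `pd` (a.u.).
#' @export
estimate_r1_pd <- function(s_pdw, s_t1w, acq = default_acquisition(),
                           b1_rel = 1, tol = 1e-9) {
  check_same_dim(s_pdw, s_t1w, "s_pdw", "s_t1w")
  validate_weighting(acq$pdw, "pdw")
  validate_weighting(acq$t1w, "t1w")
  a_pd <- deg_to_rad(acq$pdw$flip_deg) * b1_rel
  a_t1 <- deg_to_rad(acq$t1w$flip_deg) * b1_rel
  tr_pd <- ms_to_s(acq$pdw$tr_ms)
  tr_t1 <- ms_to_s(acq$t1w$tr_ms)

  den_r1 <- s_pdw / a_pd - s_t1w / a_t1
  r1 <- 0.5 * (s_t1w * a_t1 / tr_t1 - s_pdw * a_pd / tr_pd) / den_r1

  den_pd <- s_t1w * tr_pd * a_t1 - s_pdw * tr_t1 * a_pd
  pd <- s_pdw * s_t1w * (tr_pd * a_t1 / a_pd - tr_t1 * a_pd / a_t1) / den_pd

  scale_r1 <- stats::median(abs(den_r1[is.finite(den_r1)])) %||% 1
  scale_pd <- stats::median(abs(den_pd[is.finite(den_pd)])) %||% 1
  bad <- !is.finite(den_r1) | !is.finite(den_pd) |
    abs(den_r1) <= tol * max(scale_r1, .Machine$double.eps) |
    abs(den_pd) <= tol * max(scale_pd, .Machine$double.eps)
  r1[bad] <- NaN
  pd[bad] <- NaN
  list(r1 = r1, pd = pd)
}

#' Estimate MT saturation from the MT-weighted volume
#'
#' The MT-saturation map gives the percentage loss of longitudinal
#' magnetization per TR caused by the off-resonance pulse:
#' \deqn{\delta = (A \alpha / S_{mt} - 1) R1 \cdot TR - \alpha^2 / 2}
#' returned in percent units. Here `alpha` is the *nominal* MT-weighted
#' readout flip angle: when `A` and `R1` are the apparent (nominal-flip) maps
#' the transmit-field dependence of the readout cancels against the
#' pulse-power scaling of the saturation to first order (the
#' self-compensation property of the MT-saturation map), leaving only the
#' small residual corrected by [correct_mt_b1()].
#'
#' @param s_mtw MT-weighted volume (averaged echoes).
#' @param pd Apparent amplitude map `A` (same chain as `s_mtw`).
#' @param r1 Apparent R1 map, s^-1.
#' @param acq An `"mpm_acquisition"` (entry `mtw` used).
#' @return 3D array of MT saturation in p.u.; voxels with non-positive
#'   `s_mtw` are `NaN`.
#' @export
estimate_mt_sat <- function(s_mtw, pd, r1, acq = default_acquisition()) {
  check_same_dim(s_mtw, pd, "s_mtw", "pd")
  check_same_dim(s_mtw, r1, "s_mtw", "r1")
  validate_weighting(acq$mtw, "mtw")
  a <- deg_to_rad(acq$mtw$flip_deg)
  tr <- ms_to_s(acq$mtw$tr_ms)
  delta <- (pd * a / s_mtw - 1) * r1 * tr - a^2 / 2
  delta[!is.finite(s_mtw) | s_mtw <= 0] <- NaN
  100 * delta
}

#' Correct residual transmit-field dependence of the MT-saturation map
#'
#' Applies the established empirical flip-angle correction
#' `delta_corr = delta * (1 - c) / (1 - c * b1_rel)` with `c = 0.4` by
#' default; `b1_rel = 1` (nominal transmit) or `c = 0` leave the map
#' untouched.
#'
#' @param mt_sat MT-saturation map, p.u.
#' @param b1_rel Relative B1+ map.
#' @param c Correction coefficient in `[0, 1)`.
#' @return Corrected MT-saturation map; voxels with `c * b1_rel >= 1` are
#'   `NaN`.
#' @export
correct_mt_b1 <- function(mt_sat, b1_rel, c = 0.4) {
  if (!is.finite(c) || c < 0 || c >= 1)
    stop("`c` must lie in [0, 1)", call. = FALSE)
  den <- 1 - c * b1_rel
  out <- mt_sat * (1 - c) / den
  out[den <= 0] <- NaN
  out
}

#' Magnetization transfer ratio
#'
#' Classic percent signal reduction `MTR = 100 (S_ref - S_mt) / S_ref`. The
#' reference is conventionally the averaged PD-weighted volume, acquired at
#' the same nominal flip angle and TR as the MT-weighted one. Unlike the
#' MT-saturation map, MTR does not account for T1 or flip-angle variation.
#'
#' @param s_ref Reference (MT-off) volume.
#' @param s_mtw MT-weighted volume.
#' @return 3D array in p.u.; `NaN` where `s_ref <= 0`.
#' @export
compute_mtr <- function(s_ref, s_mtw) {
  check_same_dim(s_ref, s_mtw, "s_ref", "s_mtw")
  out <- 100 * (s_ref - s_mtw) / s_ref
  out[!is.finite(s_ref) | s_ref <= 0] <- NaN
  out
}

#' Run the full quantitative-map estimation chain
#'
#' From the three weighted series to quantitative maps, mirroring the
#' standard MPM processing order: (1) R2* from the log-linear fit of the
#' PD-weighted echoes; (2) collapse each weighting over its first six echoes
#' (or extrapolate to TE = 0 when `echo_handling = "te0"`); (3) apparent
#' (nominal-flip) A and R1 for the MT-saturation estimate, B1-corrected A and
#' R1 for the reported maps; (4) MT saturation with the residual flip-angle
#' correction; (5) MTR against the collapsed PD-weighted reference.
#'
#' @param series List with `pdw`, `t1w`, `mtw` `"weighted_series"` entries
#'   (as returned by [simulate_mpm()]).
#' @param acq The acquisition used.
#' @param b1_rel Relative B1+ map (scalar 1 for nominal transmit).
#' @param echo_handling `"average"` (first `n_echoes`, the standard chain) or
#'   `"te0"` (log-extrapolation to zero echo time, for validation).
#' @param n_echoes Echoes entering the average (default 6).
#' @param mt_b1_c Coefficient of [correct_mt_b1()] (default 0.4).
#' @return An object of class `"quant_maps"`: list with 3D arrays `r1`, `pd`,
#'   `mt_sat`, `r2s`, `mtr`, plus `effective_te_ms` and the call parameters.
#' @export
fit_mpm_maps <- function(series, acq = default_acquisition(), b1_rel = 1,
                         echo_handling = c("average", "te0"), n_echoes = 6L,
                         mt_b1_c = 0.4) {
  echo_handling <- match.arg(echo_handling)
  stopifnot(all(c("pdw", "t1w", "mtw") %in% names(series)))
  for (w in c("pdw", "t1w", "mtw"))
    stopifnot(inherits(series[[w]], "weighted_series"))

  r2s <- fit_r2star(series$pdw)
  s_pd <- collapse_series(series$pdw, echo_handling, n_echoes)
  s_t1 <- collapse_series(series$t1w, echo_handling, n_echoes)
  s_mt <- collapse_series(series$mtw, echo_handling, n_echoes)

  apparent <- estimate_r1_pd(s_pd, s_t1, acq, b1_rel = 1)
  corrected <- estimate_r1_pd(s_pd, s_t1, acq, b1_rel = b1_rel)

  mt <- estimate_mt_sat(s_mt, apparent$pd, apparent$r1, acq)
  mt <- correct_mt_b1(mt, b1_rel, c = mt_b1_c)
  mtr <- compute_mtr(s_pd, s_mt)

  r2s_clean <- r2s
  attr(r2s_clean, "s0") <- NULL
  structure(
    list(r1 = corrected$r1, pd = corrected$pd, mt_sat = mt,
         r2s = r2s_clean, mtr = mtr,
         effective_te_ms = attr(s_pd, "effective_te_ms"),
         echo_handling = echo_handling, n_echoes = as.integer(n_echoes)),
    class = "quant_maps"
  )
}

#' @export
print.quant_maps <- function(x, ...) {
  d <- dim(x$r1)
  ok <- is.finite(x$r1) & is.finite(x$mt_sat) & is.finite(x$r2s)
  cat("Quantitative MPM maps:", paste(d, collapse = " x "), "voxels\n")
  cat(sprintf("  valid voxels: %d / %d\n", sum(ok), length(ok)))
  cat(sprintf("  echo handling: %s (effective TE %.2f ms)\n",
              x$echo_handling, x$effective_te_ms))
  med <- function(v) stats::median(v[is.finite(v)])
  cat(sprintf("  medians: R1 %.3f s^-1, MT %.2f p.u., R2* %.1f s^-1\n",
              med(x$r1), med(x$mt_sat), med(x$r2s)))
  invisible(x)
}
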