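#' Brain mask from tissue-probability maps
#'
#' Pools the voxels entering the linear relaxometry fit: a voxel is included
#' when its grey- or white-matter probability exceeds `gmwm_threshold` and
#' its CSF probability lies below `csf_threshold` (defaults 0.5 and 0.5). CSF
#' is excluded because it contains no appreciable macromolecular or iron
#' content and is poorly characterized by the acquisition.
#'
#' `tissue_probs` is a named list of probability arrays. The white-matter map
#' is the `"wm"` entry; the grey-matter probability is the sum of all entries
#' whose name starts with `"gm"` (so cortical and deep grey count together,
#' as in standard segmentations); CSF is `"csf"`. A display-style 30% mask is
#' obtained by lowering `gmwm_threshold` alone, which always yields a
#' superset of the 50% mask; lowering the CSF threshold as well would make
#' the exclusion stricter and break that monotonicity.
#'
#' @param tissue_probs Named list of 3D probability arrays (values in [0,1]),
#'   containing `"wm"`, `"csf"` and one or more `"gm*"` entries.
#' @param gmwm_threshold Inclusion threshold on the GM and WM probabilities.
#' @param csf_threshold Exclusion threshold on the CSF probability.
#' @return Logical 3D array.
#' @export
make_mask <- function(tissue_probs, gmwm_threshold = 0.5,
                      csf_threshold = 0.5) {
  if (!is.list(tissue_probs) || is.null(names(tissue_probs)))
    stop("`tissue_probs` must be a named list of probability maps",
         call. = FALSE)
  for (t in c(gmwm_threshold, csf_threshold))
    if (!is.finite(t) || t < 0 || t > 1)
      stop("thresholds must lie in [0, 1]", call. = FALSE)
  nms <- names(tissue_probs)
  if (!"wm" %in% nms || !"csf" %in% nms)
    stop("`tissue_probs` must contain 'wm' and 'csf' maps", call. = FALSE)
  gm_names <- nms[startsWith(nms, "gm")]
  if (!length(gm_names))
    stop("`tissue_probs` must contain at least one 'gm*' map", call. = FALSE)
  rng <- range(unlist(lapply(tissue_probs, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  p_gm <- Reduce(`+`, tissue_probs[gm_names])
  (p_gm > gmwm_threshold | tissue_probs$wm > gmwm_threshold) &
    tissue_probs$csf < csf_threshold
}

#' Build the linear relaxometry design matrix
#'
#' One row per masked voxel, three columns: unity, MT saturation (p.u.) and
#' R2* (s^-1). Rows follow column-major (linear-index) voxel order, which is
#' deterministic for a given grid; the fitted coefficients are invariant to
#' any reordering. Voxels with non-finite MT or R2* inside the mask are
#' dropped from the effective mask with a warning stating the count.
#'
#' @param mt_sat MT-saturation map, p.u.
#' @param r2s R2* map, s^-1.
#' @param mask Logical array of the same grid.
#' @param terms Regressor columns after the intercept: any of `"mt"`, `"r2s"`
#'   (default both; `"mt"` alone gives the iron-ablated design).
#' @return An object of class `"relax_design"`: list with numeric matrix `m`
#'   (first column all ones), integer `voxel_index` (linear indices into the
#'   grid), `dim`, `n_dropped`.
#' @export
build_design_matrix <- function(mt_sat, r2s, mask, terms = c("mt", "r2s")) {
  check_same_dim(mt_sat, r2s, "mt_sat", "r2s")
  check_same_dim(mt_sat, mask, "mt_sat", "mask")
  if (!is.logical(mask)) stop("`mask` must be logical", call. = FALSE)
  terms <- match.arg(terms, several.ok = TRUE)
  idx <- which(mask)
  cols <- list(unity = rep(1, length(idx)))
  if ("mt" %in% terms) cols$mt <- as.vector(mt_sat)[idx]
  if ("r2s" %in% terms) cols$r2s <- as.vector(r2s)[idx]
  m <- do.call(cbind, cols)
  ok <- rowSums(!is.finite(m)) == 0L
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d masked voxel(s) with invalid regressors",
                    n_dropped), call. = FALSE)
    m <- m[ok, , drop = FALSE]
    idx <- idx[ok]
  }
  structure(
    list(m = m, voxel_index = idx, dim = dim(mask), n_dropped = n_dropped),
    class = "relax_design"
  )
}

fit_ols_design <- function(y, design, kappa_max = 1e8) {
  m <- design$m
  if (nrow(m) < ncol(m))
    stop("fewer voxels than model coefficients", call. = FALSE)
  qrm <- qr(m)
  if (qrm$rank < ncol(m) || kappa(qr.R(qrm), exact = TRUE) > kappa_max) {
    cn <- colnames(m)
    stop(sprintf(
      "design matrix is collinear beyond tolerance (columns: %s)",
      paste(cn, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrm, y)
  fitted <- as.vector(m %*% beta)
  list(beta = beta, fitted = fitted, residuals = y - fitted)
}

#' Fit the general linear relaxometry model
#'
#' Fits, by QR-based least squares over the pooled masked voxels, the
#' fast-exchange linear model
#' \deqn{R_1(r) = \beta_0 + \beta_1 MT(r) + \beta_2 R_2^*(r) + \epsilon(r)}
#' in which MT saturation acts as a surrogate for macromolecular content and
#' R2* as a surrogate for iron, and the betas are global (spatially fixed)
#' coefficients. The intercept `beta0` is the longitudinal relaxation rate of
#' free water. The fit stores the synthesized R1 (`M beta`), the residual
#' map, the Pearson correlation between synthesized and measured R1 over the
#' mask, and per-tissue residual summaries when class labels are available.
#'
#' @param r1 Measured R1 map, s^-1 (3D array).
#' @param mt_sat MT-saturation map, p.u.
#' @param r2s R2* map, s^-1.
#' @param tissue_probs Named list of probability maps used to build the mask
#'   via [make_mask()]; ignored when `mask` is supplied.
#' @param mask Optional logical array overriding the probability-based mask.
#' @param gmwm_threshold,csf_threshold Mask thresholds (see [make_mask()]).
#' @param terms Regressors after the intercept: both `"mt"` and `"r2s"`
#'   (full model) or `"mt"` alone (iron term ablated).
#' @param class_labels Optional integer array of tissue labels (with a
#'   `"levels"` attribute) for per-class residual summaries.
#' @param kappa_max Condition-number threshold above which the design is
#'   declared collinear and the fit aborts.
#' @return An object of class `"relax_fit"` with components `coefficients`,
#'   `design`, `fitted` (vector over mask rows), `residuals`, `residual_map`
#'   (3D, `NaN` outside the fitted mask), `pearson`, `sigma`, `report` (the
#'   [evaluate_fit()] summary), `dim`, `mask`, `terms`, `call`.
#' @seealso [synthesize_r1()], [evaluate_fit()], [free_water_t1()]
#' @examples
#' ph <- make_phantom(default_brain_spec(seed = 2, grid_shape = c(16, 16, 16)))
#' fit <- relax_fit(ph$r1, ph$mt_sat, ph$r2s, tissue_probs = ph$tissue_probs,
#'                  class_labels = ph$class_labels)
#' coef(fit)
#' summary(fit)
#' @export
relax_fit <- function(r1, mt_sat, r2s, tissue_probs = NULL, mask = NULL,
                      gmwm_threshold = 0.5, csf_threshold = 0.5,
                      terms = c("mt", "r2s"), class_labels = NULL,
                      kappa_max = 1e8) {
  check_same_dim(r1, mt_sat, "r1", "mt_sat")
  check_same_dim(r1, r2s, "r1", "r2s")
  if (is.null(mask)) {
    if (is.null(tissue_probs))
      stop("supply either `tissue_probs` or `mask`", call. = FALSE)
    mask <- make_mask(tissue_probs, gmwm_threshold, csf_threshold)
  }
  check_same_dim(r1, mask, "r1", "mask")

  design <- build_design_matrix(mt_sat, r2s, mask, terms = terms)
  y <- as.vector(r1)[design$voxel_index]
  ok <- is.finite(y)
  if (!all(ok)) {
    warning(sprintf("dropped %d masked voxel(s) with invalid R1",
                    sum(!ok)), call. = FALSE)
    design$m <- design$m[ok, , drop = FALSE]
    design$voxel_index <- design$voxel_index[ok]
    design$n_dropped <- design$n_dropped + sum(!ok)
    y <- y[ok]
  }
  sol <- fit_ols_design(y, design, kappa_max)

  residual_map <- array(NaN, dim(mask))
  residual_map[design$voxel_index] <- sol$residuals

  fitted_mask <- array(FALSE, dim(mask))
  fitted_mask[design$voxel_index] <- TRUE

  synth_map <- array(NaN, dim(mask))
  synth_map[design$voxel_index] <- sol$fitted
  labels <- if (!is.null(class_labels)) class_labels else NULL
  report <- evaluate_fit(r1, synth_map, fitted_mask, labels)

  p <- ncol(design$m)
  structure(
    list(coefficients = stats::setNames(as.vector(sol$beta),
                                        colnames(design$m)),
         design = design, fitted = sol$fitted, residuals = sol$residuals,
         residual_map = residual_map, pearson = report$pearson,
         sigma = sqrt(sum(sol$residuals^2) /
                        max(1, length(y) - p)),
         report = report, dim = dim(mask), mask = fitted_mask,
         terms = colnames(design$m)[-1], n = length(y),
         call = match.call()),
    class = "relax_fit"
  )
}

#' Synthesize an R1 map from fitted coefficients
#'
#' Writes the model prediction `M beta` back onto the spatial grid; voxels
#' outside the design's mask are `NaN`. The synthesized map is the model's
#' "noise-free" R1 and the basis of residual evaluation; with stable global
#' coefficients it can stand in for a measured R1 map computed from MT and
#' R2* alone.
#'
#' @param design A `"relax_design"` from [build_design_matrix()].
#' @param beta Coefficient vector matching the design columns.
#' @return 3D array of synthesized R1, s^-1.
#' @export
synthesize_r1 <- function(design, beta) {
  stopifnot(inherits(design, "relax_design"))
  if (length(beta) != ncol(design$m))
    stop(sprintf("`beta` must have length %d", ncol(design$m)),
         call. = FALSE)
  out <- array(NaN, design$dim)
  out[design$voxel_index] <- as.vector(design$m %*% beta)
  out
}

#' Evaluate agreement between measured and synthesized R1
#'
#' Computes the Pearson correlation between the two maps over the mask and
#' normalized residual summaries, `100 * (measured - synthesized) / measured`
#' in percent (positive values mean the model synthesizes R1 lower than
#' measured). With class labels, per-tissue mean and SD of the normalized
#' residuals quantify tissue-specific bias.
#'
#' @param r1_measured,r1_synth 3D maps on one grid.
#' @param mask Logical array of voxels to evaluate.
#' @param class_labels Optional integer label array with a `"levels"`
#'   attribute.
#' @return List with `pearson`, `n`, `residual_pct` (mean, sd), and
#'   `per_class` (data frame: class, n, mean_pct, sd_pct) when labels are
#'   given. If either map has zero variance over the mask the Pearson entry
#'   is `NA` with a `degenerate = TRUE` flag.
#' @export
evaluate_fit <- function(r1_measured, r1_synth, mask, class_labels = NULL) {
  check_same_dim(r1_measured, r1_synth, "r1_measured", "r1_synth")
  check_same_dim(r1_measured, mask, "r1_measured", "mask")
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  x <- as.vector(r1_measured)[idx]
  y <- as.vector(r1_synth)[idx]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  pearson <- if (degenerate) NA_real_ else stats::cor(x, y)
  res_pct <- 100 * (x - y) / x
  out <- list(pearson = pearson, degenerate = degenerate, n = length(x),
              residual_pct = c(mean = mean(res_pct), sd = stats::sd(res_pct)))
  if (!is.null(class_labels)) {
    check_same_dim(r1_measured, class_labels, "r1_measured", "class_labels")
    lab <- as.vector(class_labels)[idx][ok]
    lev <- attr(class_labels, "levels") %||%
      as.character(sort(unique(lab)))
    per <- lapply(sort(unique(lab)), function(k) {
      v <- res_pct[lab == k]
      data.frame(class = lev[k], n = length(v), mean_pct = mean(v),
                 sd_pct = stats::sd(v))
    })
    out$per_class <- do.call(rbind, per)
  }
  out
}

#' Longitudinal relaxation time of free water implied by the intercept
#'
#' Under the fast-exchange model the intercept is the relaxation rate of free
#' water, so its reciprocal is the free-water T1 in seconds.
#'
#' @param beta0 Intercept coefficient, s^-1 (> 0), or a `"relax_fit"`.
#' @return T1 of free water, seconds.
#' @export
free_water_t1 <- function(beta0) {
  if (inherits(beta0, "relax_fit")) beta0 <- beta0$coefficients[["unity"]]
  if (!is.numeric(beta0) || length(beta0) != 1L || !is.finite(beta0) ||
      beta0 <= 0)
    stop("`beta0` must be a single positive rate", call. = FALSE)
  1 / beta0
}

#' Macromolecular relaxivity implied by the MT coefficient
#'
#' The `beta1 * MT` term of the model is the product of the macromolecular
#' bound-water fraction and the relaxivity at macromolecular sites. Given a
#' representative MT saturation for a tissue and an independently measured
#' bound fraction (e.g. calorimetric), the implied relaxivity is
#' `beta1 * mt / bound_fraction` in s^-1. The result depends directly on the
#' externally supplied bound fraction, so it is exposed as a parameterized
#' quantity rather than a fixed constant.
#'
#' @param beta1 MT coefficient, s^-1 per p.u.
#' @param mt Representative tissue MT saturation, p.u. (> 0).
#' @param bound_fraction Macromolecular bound-water fraction, in (0, 1).
#' @return Relaxivity, s^-1.
#' @export
macromolecular_relaxivity <- function(beta1, mt, bound_fraction) {
  if (!is.finite(bound_fraction) || bound_fraction <= 0 ||
      bound_fraction >= 1)
    stop("`bound_fraction` must lie in (0, 1)", call. = FALSE)
  stop_if_not_positive(mt, "mt")
  beta1 * mt / bound_fraction
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.relax_fit <- function(x, digits = 4, ...) {
  cat("General linear relaxometry model fit\n")
  cat(sprintf("  %d voxels pooled (%d dropped)\n", x$n, x$design$n_dropped))
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  if (!is.na(x$pearson))
    cat(sprintf("  Pearson r (synthesized vs measured R1): %.4f\n",
                x$pearson))
  invisible(x)
}

#' @export
summary.relax_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.relax_fit")
}

#' @export
print.summary.relax_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  residual SD: %.4f s^-1\n", f$sigma))
  rp <- f$report$residual_pct
  cat(sprintf("  normalized residuals: %.2f +/- %.2f %%\n",
              rp[["mean"]], rp[["sd"]]))
  if (!is.null(f$report$per_class)) {
    cat("  per-tissue normalized residuals (%):\n")
    pc <- f$report$per_class
    for (i in seq_len(nrow(pc)))
      cat(sprintf("    %-12s %6.2f +/- %.2f  (n = %d)\n",
                  pc$class[i], pc$mean_pct[i], pc$sd_pct[i], pc$n[i]))
  }
  if ("unity" %in% names(f$coefficients) && f$coefficients[["unity"]] > 0)
    cat(sprintf("  implied free-water T1: %.3f s\n",
                free_water_t1(f$coefficients[["unity"]])))
  invisible(x)
}

#' @export
coef.relax_fit <- function(object, ...) object$coefficients

#' @export
fitted.relax_fit <- function(object, ...) object$fitted

#' Residuals of a relaxometry fit
#'
#' @param object A `"relax_fit"`.
#' @param type `"vector"` (over design rows), `"map"` (3D, `NaN` outside
#'   mask) or `"percent"` (normalized residual map, % of measured R1).
#' @param ... Unused.
#' @return Numeric vector or 3D array.
#' @export
residuals.relax_fit <- function(object, type = c("vector", "map", "percent"),
                                ...) {
  type <- match.arg(type)
  switch(type,
         vector = object$residuals,
         map = object$residual_map,
         percent = {
           meas <- object$residual_map * NaN
           meas[object$design$voxel_index] <-
             object$fitted + object$residuals
           100 * object$residual_map / meas
         })
}

#' Predict (synthesize) R1 from a relaxometry fit
#'
#' Without `newdata`, returns the synthesized R1 map over the fitted grid.
#' With `newdata` (a list carrying `mt_sat` and, for the full model, `r2s`
#' maps plus an optional logical `mask`), applies the global coefficients to
#' new maps — the "synthetic R1 from MT and R2* alone" use of the model.
#'
#' @param object A `"relax_fit"`.
#' @param newdata Optional list with `mt_sat`, `r2s` (and `mask`).
#' @param ... Unused.
#' @return 3D array of predicted R1, s^-1.
#' @export
predict.relax_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(synthesize_r1(object$design,
                                             object$coefficients))
  mask <- newdata$mask %||% array(TRUE, dim(newdata$mt_sat))
  terms <- intersect(c("mt", "r2s"),
                     c("mt", if ("r2s" %in% object$terms) "r2s"))
  r2s <- newdata$r2s %||% array(0, dim(newdata$mt_sat))
  design <- build_design_matrix(newdata$mt_sat, r2s, mask, terms = terms)
  synthesize_r1(design, object$coefficients)
}

#' Simulate measured R1 maps from a fitted relaxometry model
#'
#' Draws `nsim` synthetic "measured" R1 maps as the model prediction plus
#' i.i.d. Gaussian noise at the fit's residual SD, over the fitted mask.
#'
#' @param object A `"relax_fit"`.
#' @param nsim Number of simulated maps.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of 3D arrays of length `nsim`.
#' @export
simulate.relax_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    out <- array(NaN, object$dim)
    out[object$design$voxel_index] <- object$fitted +
      stats::rnorm(object$n, sd = object$sigma)
    out
  }
  if (!is.null(seed)) with_seed(seed, replicate(nsim, draw(),
                                                simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

#' Diagnostic plot of a relaxometry fit
#'
#' Scatter of synthesized against measured R1 over the fitted voxels with the
#' identity line, plus a histogram of the normalized residuals.
#'
#' @param x A `"relax_fit"`.
#' @param max_points Subsample cap for the scatter.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.relax_fit <- function(x, max_points = 20000L, ...) {
  meas <- x$fitted + x$residuals
  synth <- x$fitted
  if (length(meas) > max_points) {
    keep <- round(seq(1, length(meas), length.out = max_points))
    meas <- meas[keep]; synth <- synth[keep]
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(meas, synth, pch = ".", col = grDevices::grey(0.2, 0.4),
                 xlab = expression(paste("measured ", R[1], " (", s^-1, ")")),
                 ylab = expression(paste("synthesized ", R[1], " (", s^-1, ")")),
                 ...)
  graphics::abline(0, 1, col = 2)
  res_pct <- 100 * x$residuals / (x$fitted + x$residuals)
  graphics::hist(res_pct, breaks = 50, main = "",
                 xlab = "normalized residual (%)")
  invisible(x)
}
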