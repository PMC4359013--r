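toy_probs <- function(gm, wm, csf, dims = c(2, 2, 2)) {
  list(gm_cortical = array(gm, dims), wm = array(wm, dims),
       csf = array(csf, dims))
}

test_that("mask rule pools GM/WM voxels and excludes CSF as printed", {
  dims <- c(3, 1, 1)
  probs <- list(
    gm_cortical = array(c(0.6, 0.3, 0.2), dims),
    wm = array(c(0.2, 0.3, 0.6), dims),
    csf = array(c(0.3, 0.4, 0.6), dims)
  )
  m <- make_mask(probs)                 # defaults 0.5 / 0.5
  # voxel 1: GM 0.6 > 0.5, CSF 0.3 < 0.5 -> in
  # voxel 2: neither GM nor WM exceeds 0.5 -> out
  # voxel 3: WM 0.6 > 0.5 but CSF 0.6 >= 0.5 -> out
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE))
  expect_error(make_mask(probs, gmwm_threshold = 1.2), "\\[0, 1\\]")
})

test_that("lowering the GM/WM threshold to 30% yields a superset of the 50% mask", {
  ph <- make_phantom(tiny_spec(seed = 6))
  m50 <- make_mask(ph$tissue_probs, 0.5, 0.5)
  m30 <- make_mask(ph$tissue_probs, 0.3, 0.5)
  expect_true(all(m30[m50]))
  expect_gt(sum(m30), sum(m50))
  # deep and cortical grey both count towards the GM probability
  dims <- c(1, 1, 1)
  p <- list(gm_cortical = array(0.3, dims), gm_deep = array(0.3, dims),
            wm = array(0.1, dims), csf = array(0.2, dims))
  expect_true(make_mask(p)[1])
})

test_that("design matrix is built deterministically with an all-ones first column", {
  dims <- c(5, 1, 1)
  mt <- array(1:5, dims); r2s <- array(11:15, dims)
  mask <- array(TRUE, dims)
  d <- build_design_matrix(mt, r2s, mask)
  expect_equal(dim(d$m), c(5L, 3L))
  expect_true(all(d$m[, 1] == 1))
  expect_equal(d$m[, "mt"], 1:5)
  expect_equal(d$voxel_index, 1:5)
  # invalid voxel inside the mask is dropped with a warning
  r2s[3] <- NaN
  expect_warning(d2 <- build_design_matrix(mt, r2s, mask), "dropped 1")
  expect_equal(nrow(d2$m), 4L)
  expect_equal(d2$n_dropped, 1L)
  expect_error(build_design_matrix(mt, array(1, c(2, 2, 2)), mask),
               "grid mismatch")
})

test_that("fitted coefficients are invariant to voxel ordering", {
  set.seed(42)
  dims <- c(4, 4, 4)
  mt <- array(runif(64, 0.5, 2.5), dims)
  r2s <- array(runif(64, 10, 50), dims)
  y <- array(0.3 + 0.4 * mt + 0.002 * r2s + rnorm(64, sd = 0.02), dims)
  mask <- array(TRUE, dims)
  f1 <- relax_fit(y, mt, r2s, mask = mask)
  perm <- sample(64)
  f2 <- relax_fit(array(y[perm], dims), array(mt[perm], dims),
                  array(r2s[perm], dims), mask = mask)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("noiseless generating coefficients are recovered to machine precision", {
  dims <- c(4, 1, 1)
  mt <- array(c(1, 2, 1.5, 0.5), dims)
  r2s <- array(c(20, 30, 45, 15), dims)
  beta <- c(0.3, 0.4, 0.002)
  y <- array(beta[1] + beta[2] * mt + beta[3] * r2s, dims)
  fit <- relax_fit(y, mt, r2s, mask = array(TRUE, dims))
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(fit$pearson, 1, tolerance = 1e-12)
  # synthesize-then-refit is a fixed point
  synth <- predict(fit)
  refit <- relax_fit(synth, mt, r2s, mask = array(TRUE, dims))
  expect_equal(coef(refit), coef(fit), tolerance = 1e-12)
})

test_that("QR fit equals the explicit normal-equations solution on random instances", {
  set.seed(7)
  for (i in 1:20) {
    dims <- c(10, 1, 1)
    mt <- array(runif(10, 0.5, 2.5), dims)
    r2s <- array(runif(10, 10, 50), dims)
    y <- array(rnorm(10, 0.7, 0.2), dims)
    fit <- relax_fit(y, mt, r2s, mask = array(TRUE, dims))
    m <- cbind(1, as.vector(mt), as.vector(r2s))
    beta_ne <- solve(t(m) %*% m, t(m) %*% as.vector(y))
    expect_equal(unname(coef(fit)), as.vector(beta_ne), tolerance = 1e-10)
    # residual vector is orthogonal to every design column
    ip <- crossprod(m, residuals(fit))
    expect_lt(max(abs(ip)) / sum(abs(y)), 1e-8)
  }
})

test_that("synthesized R1 maps apply the coefficients voxelwise", {
  dims <- c(3, 3, 1)
  mask <- array(c(rep(TRUE, 5), rep(FALSE, 4)), dims)
  d <- build_design_matrix(array(1, dims), array(20, dims), mask)
  s <- synthesize_r1(d, c(1, 0, 0))
  expect_true(all(s[mask] == 1))
  expect_true(all(is.nan(s[!mask])))
  # single-subject example coefficients applied at MT = 1 p.u., R2* = 20 s^-1
  s2 <- synthesize_r1(d, c(0.2692, 0.3979, 0.0011))
  expect_equal(s2[1, 1, 1], 0.6891, tolerance = 1e-12)
  expect_error(synthesize_r1(d, c(1, 2)), "length 3")
})

test_that("fit evaluation reports Pearson and normalized residuals correctly", {
  dims <- c(4, 4, 1)
  mask <- array(TRUE, dims)
  x <- array(seq(0.5, 2, length.out = 16), dims)
  ev <- evaluate_fit(x, x, mask)
  expect_equal(ev$pearson, 1)
  expect_equal(unname(ev$residual_pct["mean"]), 0)
  ev2 <- evaluate_fit(x, -x, mask)
  expect_equal(ev2$pearson, -1)
  ev3 <- evaluate_fit(array(1, dims), array(1, dims), mask)
  expect_true(ev3$degenerate)
  expect_true(is.na(ev3$pearson))
})

test_that("collinear designs abort with an explicit error", {
  dims <- c(6, 1, 1)
  mt <- array(1:6 / 2, dims)
  expect_error(
    relax_fit(array(1, dims), mt, mt * 2, mask = array(TRUE, dims)),
    "collinear")
})

test_that("free-water T1 is the reciprocal intercept", {
  expect_equal(free_water_t1(1), 1)
  expect_equal(free_water_t1(0.5), 2)
  expect_error(free_water_t1(0), "positive")
  dims <- c(4, 1, 1)
  mt <- array(c(1, 2, 1.5, 0.5), dims); r2s <- array(c(20, 30, 45, 15), dims)
  y <- array(0.25 + 0.4 * mt + 0.002 * r2s, dims)
  fit <- relax_fit(y, mt, r2s, mask = array(TRUE, dims))
  expect_equal(free_water_t1(fit), 4, tolerance = 1e-9)
})

test_that("macromolecular relaxivity arithmetic and scaling hold", {
  expect_equal(macromolecular_relaxivity(0.4, 2, 0.2), 4)
  expect_equal(macromolecular_relaxivity(0.4, 2, 0.4),
               macromolecular_relaxivity(0.4, 2, 0.2) / 2)
  expect_error(macromolecular_relaxivity(0.4, 2, 0), "\\(0, 1\\)")
  # with the cohort-mean MT coefficient and plausible WM values the implied
  # relaxivity lands in the low single digits of s^-1
  r <- macromolecular_relaxivity(default_relax_beta()[["beta1"]],
                                 mt = 2, bound_fraction = 0.25)
  expect_gt(r, 1)
  expect_lt(r, 10)
})

test_that("coefficients are recovered under noise and Pearson degrades monotonically", {
  gen <- function(n, noise_sd, seed) {
    set.seed(seed)
    dims <- c(n, 1, 1)
    mt <- array(runif(n, 0.5, 2.5), dims)
    r2s <- array(runif(n, 10, 50), dims)
    beta <- default_relax_beta()
    y <- array(beta[1] + beta[2] * mt + beta[3] * r2s +
                 rnorm(n, sd = noise_sd), dims)
    relax_fit(y, mt, r2s, mask = array(TRUE, dims))
  }
  fits <- lapply(1:5, function(s) gen(20000, 0.05, s))
  bmean <- rowMeans(vapply(fits, coef, numeric(3)))
  beta <- default_relax_beta()
  expect_lt(abs(bmean[1] / beta[1] - 1), 0.01)
  expect_lt(abs(bmean[2] / beta[2] - 1), 0.01)
  expect_lt(abs(bmean[3] / beta[3] - 1), 0.10)
  pears <- vapply(c(0.02, 0.05, 0.1, 0.2), function(ns)
    gen(20000, ns, seed = 123)$pearson, 0)
  expect_true(all(diff(pears) < 0))
})

test_that("predict and simulate methods are consistent with the fit", {
  dims <- c(4, 4, 1)
  set.seed(9)
  mt <- array(runif(16, 0.5, 2.5), dims)
  r2s <- array(runif(16, 10, 50), dims)
  y <- array(0.3 + 0.4 * mt + 0.002 * r2s + rnorm(16, sd = 0.01), dims)
  fit <- relax_fit(y, mt, r2s, mask = array(TRUE, dims))
  pr <- predict(fit, newdata = list(mt_sat = mt, r2s = r2s))
  expect_equal(pr, predict(fit), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_identical(simulate(fit, nsim = 2, seed = 4), sims)
  expect_equal(dim(sims[[1]]), dims)
})
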