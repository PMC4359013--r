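make_series <- function(signal_fun, te, weighting = "pdw", dims = c(3, 3, 3),
                        flip = 6, tr = 23.7) {
  s <- signal_fun(te)                      # vector over echoes
  vol <- array(rep(s, each = prod(dims)), c(dims, length(te)))
  weighted_series(weighting, vol,
                  list(flip_deg = flip, tr_ms = tr, te_ms = te))
}

test_that("log-linear R2* fit is exact on exponential decay over the default echo grid", {
  te <- default_acquisition()$pdw$te_ms
  expect_equal(max(te), 19.7)
  ser <- make_series(function(te) 100 * exp(-0.03 * te), te)
  r2s <- fit_r2star(ser)
  expect_equal(as.vector(r2s), rep(30, length(r2s)), tolerance = 1e-12)
  expect_equal(as.vector(attr(r2s, "s0")), rep(100, length(r2s)),
               tolerance = 1e-12)
})

test_that("constant echoes give zero R2* and two echoes give the closed form", {
  te <- c(3, 11)
  ser0 <- make_series(function(te) rep(42, length(te)), te)
  expect_equal(as.vector(fit_r2star(ser0)), rep(0, 27))
  ser2 <- make_series(function(te) c(90, 60), te)
  want <- log(90 / 60) / ((11 - 3) / 1000)
  expect_equal(as.vector(fit_r2star(ser2)), rep(want, 27), tolerance = 1e-12)
})

test_that("voxels with non-positive echoes are flagged invalid", {
  te <- c(3, 6, 9)
  vol <- array(50, c(2, 2, 2, 3))
  vol[1, 1, 1, 2] <- 0
  ser <- weighted_series("pdw", vol, list(flip_deg = 6, tr_ms = 23.7,
                                          te_ms = te))
  r2s <- fit_r2star(ser)
  expect_true(is.nan(r2s[1, 1, 1]))
  expect_false(anyNA(r2s[-1]))
})

test_that("echo averaging records the effective echo time and averages correctly", {
  te <- default_acquisition()$pdw$te_ms
  ser <- make_series(function(te) rep(7, length(te)), te)
  avg <- average_echoes(ser, 6)
  expect_equal(attr(avg, "effective_te_ms"), 8.45)
  expect_true(all(avg == 7))                      # idempotent on equal echoes
  ser2 <- make_series(function(te) c(1, 3), c(3, 11))
  expect_true(all(average_echoes(ser2, 2) == 2))
  expect_error(average_echoes(ser, 0), "at least 1")
  expect_error(average_echoes(ser, 9), "exceeds")
})

test_that("dual flip-angle inversion recovers R1 and PD within 2% at nominal transmit", {
  acq <- default_acquisition()
  s_pd <- const_vol(flash_signal(1000, 1, 0, acq$pdw$flip_deg,
                                 acq$pdw$tr_ms, 0))
  s_t1 <- const_vol(flash_signal(1000, 1, 0, acq$t1w$flip_deg,
                                 acq$t1w$tr_ms, 0))
  est <- estimate_r1_pd(s_pd, s_t1, acq, b1_rel = 1)
  expect_lt(max(abs(est$r1 - 1)), 0.02)
  expect_lt(max(abs(est$pd / 1000 - 1)), 0.02)
})

test_that("B1-corrected inversion at reduced transmit matches the nominal case", {
  acq <- default_acquisition()
  b1 <- 0.8
  s_pd <- const_vol(flash_signal(1000, 1, 0, acq$pdw$flip_deg * b1,
                                 acq$pdw$tr_ms, 0))
  s_t1 <- const_vol(flash_signal(1000, 1, 0, acq$t1w$flip_deg * b1,
                                 acq$t1w$tr_ms, 0))
  est_b1 <- estimate_r1_pd(s_pd, s_t1, acq, b1_rel = const_vol(b1))

  s_pd0 <- const_vol(flash_signal(1000, 1, 0, acq$pdw$flip_deg,
                                  acq$pdw$tr_ms, 0))
  s_t10 <- const_vol(flash_signal(1000, 1, 0, acq$t1w$flip_deg,
                                  acq$t1w$tr_ms, 0))
  est_0 <- estimate_r1_pd(s_pd0, s_t10, acq, b1_rel = 1)
  # both recover the truth; they agree with each other only to the order of
  # the flip-dependent rational-approximation bias (< 1%)
  expect_lt(max(abs(est_b1$r1 - 1)), 0.02)
  expect_lt(max(abs(est_b1$pd / 1000 - 1)), 0.02)
  expect_equal(est_b1$r1, est_0$r1, tolerance = 0.01)
  expect_equal(est_b1$pd, est_0$pd, tolerance = 0.01)
})

test_that("degenerate contrast (equal signals, flips and TRs) is flagged invalid", {
  acq <- default_acquisition()
  acq$t1w <- acq$pdw
  s <- const_vol(50)
  est <- estimate_r1_pd(s, s, acq, b1_rel = 1)
  expect_true(all(is.nan(est$r1)))
  expect_true(all(is.nan(est$pd)))
})

test_that("MT saturation is exactly zero for the rational no-saturation signal", {
  acq <- default_acquisition()
  a <- acq$mtw$flip_deg * pi / 180
  tr <- acq$mtw$tr_ms / 1000
  A <- 900; r1 <- 0.8
  s_mt <- const_vol(A * a * r1 * tr / (a^2 / 2 + r1 * tr))
  delta <- estimate_mt_sat(s_mt, const_vol(A), const_vol(r1), acq)
  expect_equal(as.vector(delta), rep(0, 64), tolerance = 1e-10)
  # scale invariance: common scaling of A and S_mt cancels exactly
  delta2 <- estimate_mt_sat(s_mt * 3.7, const_vol(A * 3.7), const_vol(r1),
                            acq)
  expect_equal(delta2, delta, tolerance = 1e-12)
})

test_that("forward-simulated saturation of 2 p.u. is recovered within 5%", {
  acq <- default_acquisition()
  s_pd <- const_vol(flash_signal(1000, 0.9, 0, acq$pdw$flip_deg,
                                 acq$pdw$tr_ms, 0))
  s_t1 <- const_vol(flash_signal(1000, 0.9, 0, acq$t1w$flip_deg,
                                 acq$t1w$tr_ms, 0))
  est <- estimate_r1_pd(s_pd, s_t1, acq, b1_rel = 1)
  s_mt <- const_vol(mt_flash_signal(1000, 0.9, 0, 2, acq$mtw$flip_deg,
                                    acq$mtw$tr_ms, 0))
  delta <- estimate_mt_sat(s_mt, est$pd, est$r1, acq)
  expect_lt(max(abs(delta / 2 - 1)), 0.05)
  expect_true(is.nan(estimate_mt_sat(const_vol(-1), est$pd, est$r1,
                                     acq)[1]))
})

test_that("MT flip-angle correction follows its stated algebra", {
  expect_equal(correct_mt_b1(1, b1_rel = 0.5, c = 0.4), 0.75)
  x <- const_vol(2.3)
  expect_equal(correct_mt_b1(x, b1_rel = const_vol(1), c = 0.4), x)
  expect_equal(correct_mt_b1(x, b1_rel = const_vol(0.7), c = 0), x)
  expect_true(is.nan(correct_mt_b1(1, b1_rel = 3, c = 0.4)))
  expect_error(correct_mt_b1(1, 1, c = 1), "\\[0, 1\\)")
})

test_that("MTR follows its definition", {
  expect_equal(compute_mtr(const_vol(100), const_vol(80)),
               const_vol(20))
  expect_equal(compute_mtr(const_vol(50), const_vol(50)), const_vol(0))
  expect_equal(compute_mtr(const_vol(50), const_vol(0)), const_vol(100))
  expect_true(all(is.nan(compute_mtr(const_vol(0), const_vol(1)))))
})

test_that("noiseless end-to-end map estimation recovers ground truth within 5%", {
  ph <- make_phantom(default_brain_spec(seed = 8, grid_shape = c(16, 16, 16)))
  series <- simulate_mpm(ph, noise_sd = 0)
  maps <- fit_mpm_maps(series, b1_rel = ph$b1_rel, echo_handling = "te0")
  mask <- make_mask(ph$tissue_probs)
  relerr <- function(est, truth) max(abs((est[mask] - truth[mask]) /
                                           truth[mask]))
  expect_lt(relerr(maps$r1, ph$r1), 0.05)
  expect_lt(relerr(maps$pd, ph$pd), 0.05)
  expect_lt(relerr(maps$mt_sat, ph$mt_sat), 0.05)
  expect_lt(relerr(maps$r2s, ph$r2s), 1e-6)       # exact exponentials
  # MT-saturation correction at nominal transmit is the identity on delta
  expect_equal(correct_mt_b1(maps$mt_sat, 1, c = 0.4), maps$mt_sat)
  # MTR and MT saturation increase together on noiseless single-class data
  cl <- function(d) tissue_class("wm", r1 = 1, pd = 700, mt_sat = d,
                                 r2s = 20, within_class_sd = 0)
  vals <- vapply(c(0.5, 1, 2, 4), function(d) {
    s <- phantom_spec(grid_shape = c(8, 8, 8), classes = list(cl(d)),
                      model_beta = NULL, b1_range = c(1, 1), seed = 1)
    p <- make_phantom(s)
    m <- fit_mpm_maps(simulate_mpm(p, noise_sd = 0), b1_rel = p$b1_rel)
    c(m$mt_sat[1], m$mtr[1])
  }, c(0, 0))
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
})
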