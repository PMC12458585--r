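make_signal <- function(abscissa, value, TR = NULL) {
  s <- tibble::tibble(protocol_id = "syn", abscissa = abscissa, value = value)
  if (!is.null(TR)) attr(s, "TR") <- TR
  s
}

test_that("each fitter recovers T1 exactly from its own noiseless model", {
  TI <- c(0.05, 0.1, 0.3, 0.8, 1.5, 3, 5)
  f <- fit_inversion_recovery(make_signal(TI, 1 - 2 * exp(-TI / 0.8)))
  expect_equal(f$T1o, 0.8, tolerance = 1e-9)
  expect_true(f$converged)

  TS <- c(0.1, 0.4, 1, 2.5, 6)
  f <- fit_saturation_recovery(make_signal(TS, 3 * (1 - exp(-TS / 1.2))))
  expect_equal(f$T1o, 1.2, tolerance = 1e-9)
  expect_equal(f$scale, 3, tolerance = 1e-9)

  # Look-Locker apparent recovery with known amplitudes: ratio correction
  t <- seq(0.05, 6, length.out = 20)
  A <- 0.4
  B <- 0.9
  T1star <- 1.1
  f <- fit_look_locker(make_signal(t, A - B * exp(-t / T1star)))
  expect_equal(f$T1o, T1star * (B / A - 1), tolerance = 1e-9)
  expect_equal(f$aux$T1star, T1star, tolerance = 1e-9)

  # DESPOT1 on exact Ernst signals
  a <- c(4, 18) * pi / 180
  TR <- 0.015
  E1 <- exp(-TR / 0.9)
  f <- fit_vfa_despot1(make_signal(a, sin(a) * (1 - E1) / (1 - E1 * cos(a)),
                                   TR = TR))
  expect_equal(f$T1o, 0.9, tolerance = 1e-8)
  expect_equal(f$aux$slope, E1, tolerance = 1e-8)
})

test_that("fitted T1 is invariant under signal rescaling", {
  TI <- c(0.05, 0.2, 0.6, 1.4, 3, 6)
  y <- 1 - 1.95 * exp(-TI / 1.1)
  f1 <- fit_inversion_recovery(make_signal(TI, y))
  f2 <- fit_inversion_recovery(make_signal(TI, 7.3 * y))
  expect_equal(f1$T1o, f2$T1o, tolerance = 1e-9)

  TS <- c(0.1, 0.5, 1.5, 4)
  y <- 1 - exp(-TS / 0.7)
  expect_equal(fit_saturation_recovery(make_signal(TS, y))$T1o,
               fit_saturation_recovery(make_signal(TS, 0.2 * y))$T1o,
               tolerance = 1e-9)

  a <- c(3, 8, 15) * pi / 180
  E1 <- exp(-0.012 / 1.5)
  y <- sin(a) * (1 - E1) / (1 - E1 * cos(a))
  expect_equal(fit_vfa_despot1(make_signal(a, y, TR = 0.012))$T1o,
               fit_vfa_despot1(make_signal(a, 42 * y, TR = 0.012))$T1o,
               tolerance = 1e-9)

  t <- seq(0.1, 8, length.out = 15)
  y <- 0.5 - 1.1 * exp(-t / 1.3)
  expect_equal(fit_look_locker(make_signal(t, y))$T1o,
               fit_look_locker(make_signal(t, 3 * y))$T1o,
               tolerance = 1e-9)
})

test_that("Bloch-limit simulations are fitted back to T1f", {
  p <- bloch_params(T1f = 1.084)
  suite <- default_protocol_suite()
  f <- observed_t1(suite$ir01, p)
  expect_equal(f$T1o, 1.084, tolerance = 1e-6)
  f <- observed_t1(suite$sr01, p)
  expect_equal(f$T1o, 1.084, tolerance = 1e-4)
  f <- observed_t1(suite$vfa02, p)
  expect_equal(f$T1o, 1.084, tolerance = 1e-3)
})

test_that("Look-Locker corrections behave as documented in the Bloch limit", {
  p <- bloch_params(T1f = 1.4)
  pr_ratio <- ll_protocol("llr", 5 * pi / 180, 0.15, 32, 12, delay1 = 0.05,
                          inv_dur = 0.010, exc_dur = 1e-4,
                          ll_correction = "ratio")
  s <- simulate_signals(pr_ratio, p)
  f_ratio <- fit_look_locker(s)
  expect_true(f_ratio$converged)
  expect_equal(f_ratio$T1o, 1.4, tolerance = 0.01)  # classic correction: ~1%
  f_fa <- fit_look_locker(s, correction = "flip_angle", flip = 5 * pi / 180,
                          spacing = 0.15)
  expect_equal(f_fa$T1o, 1.4, tolerance = 1e-3)     # rate correction: exact
})

test_that("MP2RAGE lookup inverts itself and the ratio is scale-invariant", {
  suite <- default_protocol_suite()
  pr <- suite$mp01
  p <- bloch_params(T1f = 1.4)
  s <- simulate_signals(pr, p)
  f <- fit_mp2rage(s, pr)
  expect_true(f$converged)
  expect_equal(f$T1o, 1.4, tolerance = 1e-3)
  s2 <- s
  s2$value <- 3.7 * s2$value
  expect_equal(fit_mp2rage(s2, pr)$T1o, f$T1o, tolerance = 1e-12)
  lk <- mp2rage_lookup(pr)
  expect_true(lk$monotone)
  expect_true(all(diff(lk$U) > 0) || all(diff(lk$U) < 0))
  # the calibration branch covers the physiological range of observed T1
  expect_lt(min(lk$T1), 0.45)
  expect_gt(max(lk$T1), 2.4)
})

test_that("under MT the observed T1 is biased away from T1f and the bias is
           method-dependent", {
  p <- wm_params()
  suite <- default_protocol_suite()
  t1o_ir <- observed_t1(suite$ir01, p)$T1o
  t1o_vfa <- observed_t1(suite$vfa01, p)$T1o
  expect_gt(abs(t1o_ir - p$T1f), 0.1)   # far from T1f: MT bias is real
  expect_gt(abs(t1o_vfa - p$T1f), 0.1)
  # the two families disagree with each other, not just with T1f
  expect_gt(abs(t1o_vfa - t1o_ir), 0.05)
})

test_that("saturation-recovery T1o responds smoothly to the pool size", {
  pr <- default_protocol_suite()$sr01
  t1o <- vapply(c(0.20, 0.21, 0.22), function(m) {
    observed_t1(pr, mt_params(m, 1.84, 0.065, 0.05, 0.34, 1e-5))$T1o
  }, numeric(1))
  expect_true(all(diff(t1o) < 0) || all(diff(t1o) > 0))
})

test_that("tidiers return the documented shapes", {
  TI <- c(0.1, 0.5, 2)
  f <- fit_inversion_recovery(make_signal(TI, 1 - 2 * exp(-TI / 0.8)))
  expect_named(tidy(f), c("term", "estimate"))
  expect_equal(glance(f)$T1o, 0.8, tolerance = 1e-6)
})
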