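test_that("default suite has the documented composition", {
  suite <- default_protocol_suite()
  expect_length(suite, 25)
  counts <- table(vapply(suite, `[[`, "", "type"))
  expect_equal(unname(counts[c("variable_flip_angle", "inversion_recovery",
                               "saturation_recovery", "look_locker",
                               "mp2rage")]),
               c(12L, 8L, 1L, 2L, 2L), ignore_attr = TRUE)
  ids <- vapply(suite, `[[`, "", "id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("every default protocol simulates for WM-like parameters", {
  p <- wm_params()
  for (pr in default_protocol_suite()) {
    s <- simulate_signals(pr, p)
    expect_true(all(is.finite(s$value)), info = pr$id)
    expect_gt(nrow(s), 1)
  }
})

test_that("Bloch-limit signals match the textbook closed forms", {
  T1 <- 1.084
  p <- bloch_params(T1f = T1)
  # ideal single-shot IR: S(TI) = 1 - 2 exp(-TI/T1)
  ir <- ir_protocol("ir_ideal", c(0.1, 0.8, 2.5), TR = 40, inv_dur = 0,
                    exc_dur = 0)
  s <- simulate_signals(ir, p)
  expect_equal(s$value, 1 - 2 * exp(-s$abscissa / T1), tolerance = 1e-8)
  # spoiled steady state: Ernst equation
  vfa <- vfa_protocol("vfa_ideal", c(2, 5, 11, 19) * pi / 180, 0.015,
                      exc_dur = 0)
  s <- simulate_signals(vfa, p)
  E1 <- exp(-0.015 / T1)
  expect_equal(s$value,
               sin(s$abscissa) * (1 - E1) / (1 - E1 * cos(s$abscissa)),
               tolerance = 1e-8)
  # saturation recovery: S(TS) = 1 - exp(-TS/T1)
  sr <- sr_protocol("sr_ideal", c(0.2, 1, 3), 20, sat_dur = 0, exc_dur = 0)
  s <- simulate_signals(sr, p)
  expect_equal(s$value, 1 - exp(-s$abscissa / T1), tolerance = 1e-8)
})

test_that("converged cycles are periodic", {
  p <- wm_params()
  pr <- vfa_protocol("v", c(4, 18) * pi / 180, 0.015, 1e-4)
  P_exc <- t1sens:::pulse_propagator(rf_pulse(4 * pi / 180, 1e-4), p)
  ops <- list(P_exc, t1sens:::spoil_matrix(),
              unclass(free_propagator(p, 0.015 - 1e-4)))
  C <- t1sens:::cycle_matrix(ops)
  s_ss <- t1sens:::steady_state(C, equilibrium_state(p))
  expect_lt(max(abs(C %*% s_ss - s_ss)), 1e-8)
})

test_that("IR and SR recoveries are monotone in the recovery time", {
  p <- wm_params()
  suite <- default_protocol_suite()
  expect_true(all(diff(simulate_signals(suite$ir01, p)$value) > 0))
  expect_true(all(diff(simulate_signals(suite$sr01, p)$value) > 0))
})

test_that("MT recovery is bi-exponential: mono-exponential fits leave
           structured residuals", {
  p <- wm_params()
  s <- simulate_signals(default_protocol_suite()$ir04, p)
  fit <- fit_inversion_recovery(s)
  expect_true(fit$converged)
  expect_gt(fit$rms_residual, 1e-6)
})

test_that("protocol YAML round-trips losslessly", {
  suite <- default_protocol_suite()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocols(suite, path)
  back <- load_protocols(path)
  expect_equal(names(back), names(suite))
  for (id in names(suite)) {
    expect_equal(back[[id]], suite[[id]], tolerance = 1e-12, info = id)
  }
})

test_that("protocol files are validated with named fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("protocols:",
               "- id: bad_vfa",
               "  type: variable_flip_angle",
               "  flips: [4.0, 18.0]"), path)
  expect_error(load_protocols(path), "TR")
  writeLines(c("protocols:",
               "- id: x",
               "  type: no_such_type",
               "  TR: 1.0"), path)
  expect_error(load_protocols(path), "type")
  # degrees in the file become radians internally
  writeLines(c("protocols:",
               "- id: v",
               "  type: variable_flip_angle",
               "  flips: [90.0, 10.0]",
               "  TR: 0.02"), path)
  pr <- load_protocols(path)$v
  expect_equal(pr$flips[1], pi / 2, tolerance = 1e-12)
})

test_that("protocol constructors reject inconsistent timing", {
  expect_error(ir_protocol("x", c(0.5, 0.2, 1), 10), "increasing")
  expect_error(ir_protocol("x", c(0.2, 0.5), 10), "TI")
  expect_error(vfa_protocol("x", c(0.1, 0.1), 0.015), "flips")
  expect_error(sr_protocol("x", c(1, 2, 3), 2), "TR")
  expect_error(mp2rage_protocol("x", 2, 1, c(0.1, 0.1), 0.008, 8, 6), "TI2")
})
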