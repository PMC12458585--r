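test_that("parameter validation enforces the physical domain", {
  expect_error(mt_params(0.2, -1, 0.06, 0.05, 0.3, 1e-5), "T1f")
  expect_error(mt_params(1.2, 1.8, 0.06, 0.05, 0.3, 1e-5), "m0s")
  expect_error(mt_params(0.2, 1.8, 0.06, 0.05, 0.3, NaN), "finite")
  # small negative m0s is admitted (finite-difference stencils at the
  # Bloch limit), large negative is not
  expect_silent(mt_params(-0.01, 1.8, 0.06, 0.05, 0.3, 1e-5))
  expect_error(mt_params(-0.2, 1.8, 0.06, 0.05, 0.3, 1e-5), "m0s")
})

test_that("thermal equilibrium is a fixed point of the free dynamics", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_params()
    eq <- equilibrium_state(p)
    A <- relaxation_exchange_generator(p)
    expect_lt(max(abs(A %*% eq)), 1e-12)
    for (dt in c(1e-3, 0.1, 2)) {
      expect_lt(max(abs(free_propagator(p, dt) %*% eq - eq)), 1e-10)
    }
  }
})

test_that("the m0s = 0 limit reduces to mono-exponential Bloch recovery", {
  p <- bloch_params(T1f = 1.4)
  for (zf0 in c(-1, 0, 0.5)) {
    s <- c(0, 0, zf0, 0, 1)
    for (t in c(0.05, 0.7, 3)) {
      zf <- (free_propagator(p, t) %*% s)[3]
      expect_equal(zf, 1 + (zf0 - 1) * exp(-t / 1.4), tolerance = 1e-9)
    }
  }
})

test_that("exchange pulls a perturbed state toward equilibrium", {
  p <- wm_params()
  s <- c(0, 0, 1 - p$m0s, 0, 1)  # free pool full, semi-solid pool empty
  A <- relaxation_exchange_generator(p)
  ds <- as.vector(A %*% s)
  expect_lt(ds[3], 0)
  expect_gt(ds[4], 0)
  # direction agrees with a dense ODE solve over a short interval
  s_ode <- ode_oracle(A, s, 1e-3)
  expect_lt(s_ode[3], s[3])
  expect_gt(s_ode[4], s[4])
})

test_that("free propagator: identity, semigroup, relaxation limit", {
  p <- wm_params()
  expect_equal(unclass(free_propagator(p, 0)), diag(5), ignore_attr = TRUE)
  expect_error(free_propagator(p, -1), "dt")
  P1 <- free_propagator(p, 0.3)
  P2 <- free_propagator(p, 1.1)
  P12 <- free_propagator(p, 1.4)
  expect_lt(max(abs(P2 %*% P1 - P12)), 1e-10)
  # long evolution relaxes any physical state to equilibrium
  s <- c(0.2, -0.1, -0.5, 0.05, 1)
  s_inf <- free_propagator(p, 20 * max(p$T1f, p$T1s)) %*% s
  expect_lt(max(abs(s_inf - equilibrium_state(p))), 1e-6)
})

test_that("internal matrix exponential matches Matrix::expm", {
  set.seed(7)
  for (i in 1:10) {
    A <- matrix(stats::rnorm(25, sd = 5), 5, 5)
    expect_lt(max(abs(t1sens:::expm_pade(A) -
                        as.matrix(Matrix::expm(A)))) /
                max(abs(as.matrix(Matrix::expm(A)))), 1e-12)
  }
})

test_that("absorption lineshapes have their closed-form on-resonance values", {
  p <- wm_params()
  expect_identical(semisolid_saturation_rate(0, p), 0)
  # Lorentzian: G(0) = T2s / pi, so R_rf = omega1^2 * T2s
  w1 <- 800
  expect_equal(semisolid_saturation_rate(w1, p, "lorentzian"),
               w1^2 * p$T2s, tolerance = 1e-12)
  expect_equal(semisolid_saturation_rate(w1, p, "gaussian"),
               pi * w1^2 * p$T2s / sqrt(2 * pi), tolerance = 1e-12)
  expect_error(semisolid_saturation_rate(w1, p, "boxcar"))
})

test_that("super-Lorentzian value matches independent quadrature at the
           interpolation offset", {
  T2s <- 1e-5
  delta <- 1500
  # independent oracle: trapezoid rule on a fine grid of the orientation
  # integral
  u <- seq(0, 1, length.out = 2e5 + 1)
  d <- abs(3 * u^2 - 1)
  f <- ifelse(d > 1e-12,
              sqrt(2 / pi) / d * exp(-2 * (2 * pi * delta * T2s / d)^2), 0)
  g_trap <- T2s * (sum(f) - (f[1] + f[length(f)]) / 2) / 2e5
  expect_equal(t1sens:::lineshape_g(delta, T2s, "super_lorentzian"),
               g_trap, tolerance = 1e-6)
  # on-resonance value from quadratic interpolation is finite, positive,
  # and larger than the 1.5 kHz value (G increases toward resonance)
  g0 <- t1sens:::super_lorentzian_g0(T2s)
  expect_gt(g0, g_trap)
  expect_lt(g0, 10 * T2s)
})

test_that("rectangular pulse propagator: limits and dense-ODE oracle", {
  p <- wm_params()
  # zero flip degenerates to free evolution
  P0 <- rect_pulse_propagator(rf_pulse(0, 1e-3), p)
  expect_lt(max(abs(P0 - free_propagator(p, 1e-3))), 1e-12)
  # pi pulse inverts the free pool but only partially saturates the
  # semi-solid pool
  s <- equilibrium_state(p)
  s1 <- as.vector(rect_pulse_propagator(rf_pulse(pi, 1e-3), p) %*% s)
  expect_equal(s1[3], -(1 - p$m0s), tolerance = 0.05)
  expect_gt(s1[4], 0)
  expect_lt(s1[4], p$m0s)
  # oracle equivalence on randomized draws
  set.seed(11)
  for (i in 1:4) {
    q <- random_params()
    flip <- stats::runif(1, 0.1, pi)
    dur <- stats::runif(1, 2e-4, 5e-3)
    pulse <- rf_pulse(flip, dur, phase = stats::runif(1, 0, 2 * pi))
    w1 <- flip / dur
    G <- relaxation_exchange_generator(q) +
      t1sens:::rotation_generator(w1, pulse$phase)
    G[4, 4] <- G[4, 4] - semisolid_saturation_rate(w1, q)
    s0 <- equilibrium_state(q)
    expect_equal(as.vector(rect_pulse_propagator(pulse, q) %*% s0),
                 ode_oracle(G, s0, dur), tolerance = 1e-7)
  }
})

test_that("shaped pulse propagator: degenerate cases and RK4 order", {
  p <- wm_params()
  dur <- 1e-3
  flip <- pi / 2
  # constant envelope degenerates to the rectangular propagator
  const <- rf_pulse(flip, dur, envelope = function(t) {
    rep(flip / dur, length(t))
  })
  Pr <- rect_pulse_propagator(rf_pulse(flip, dur), p)
  Ps <- shaped_pulse_propagator(const, p, n_steps = 200)
  expect_lt(max(abs(Ps - Pr)), 1e-8)
  # zero-amplitude envelope equals free evolution
  zero <- rf_pulse(0, dur, envelope = function(t) rep(0, length(t)))
  expect_lt(max(abs(shaped_pulse_propagator(zero, p, 50) -
                      free_propagator(p, dur))), 1e-12)
  # 4th-order convergence: halving the step cuts the error ~16x
  hann <- rf_pulse(flip, dur, envelope = function(t) {
    flip / dur * (1 - cos(2 * pi * t / dur))
  })
  ref <- shaped_pulse_propagator(hann, p, n_steps = 2048)
  e1 <- max(abs(shaped_pulse_propagator(hann, p, 16) - ref))
  e2 <- max(abs(shaped_pulse_propagator(hann, p, 32) - ref))
  expect_gt(e1 / e2, 10)
  expect_lt(e1 / e2, 24)
  # envelope must integrate to the flip angle
  expect_error(rf_pulse(flip, dur, envelope = function(t) rep(1, length(t))),
               "integrate")
})

test_that("instantaneous rotations act on the free pool only", {
  p <- wm_params()
  expect_equal(unclass(instantaneous_rotation(0)), diag(5),
               ignore_attr = TRUE)
  s1 <- as.vector(instantaneous_rotation(pi) %*% equilibrium_state(p))
  expect_equal(s1[3], -(1 - p$m0s), tolerance = 1e-12)
  expect_equal(s1[4], p$m0s, tolerance = 1e-12)
  back <- instantaneous_rotation(-0.7, 0.3) %*%
    instantaneous_rotation(0.7, 0.3)
  expect_lt(max(abs(back - diag(5))), 1e-12)
})

test_that("spoiling zeroes the transverse components and is idempotent", {
  s <- c(0.3, -0.1, 0.5, 0.1, 1)
  expect_identical(spoil(s), c(0, 0, 0.5, 0.1, 1))
  expect_identical(spoil(spoil(s)), spoil(s))
  p <- wm_params()
  expect_identical(spoil(equilibrium_state(p)), equilibrium_state(p))
})

test_that("longitudinal components stay inside the physical set", {
  set.seed(23)
  for (i in 1:3) {
    p <- random_params()
    m0f <- 1 - p$m0s
    s <- equilibrium_state(p)
    for (k in 1:20) {
      op <- sample(3, 1)
      s <- switch(op,
        as.vector(free_propagator(p, stats::runif(1, 0, 1)) %*% s),
        as.vector(rect_pulse_propagator(
          rf_pulse(stats::runif(1, 0, pi), 1e-3), p) %*% s),
        spoil(s))
      expect_lte(abs(s[3]), m0f + 1e-9)
      expect_lte(abs(s[4]), p$m0s + 1e-9)
    }
  }
})

test_that("propagators preserve the homogeneous component", {
  p <- wm_params()
  for (P in list(free_propagator(p, 0.5),
                 rect_pulse_propagator(rf_pulse(1, 1e-3), p),
                 instantaneous_rotation(1.2, 0.4))) {
    expect_equal(unclass(P)[5, ], c(0, 0, 0, 0, 1), ignore_attr = TRUE)
  }
})
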