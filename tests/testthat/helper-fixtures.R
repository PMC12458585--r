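# shared fixtures: parameter sets, small protocols, dense-ODE oracle

wm_params <- function() {
  mt_params(m0s = 0.25, T1f = 1.84, T2f = 0.065, Tx = 0.05,
            T1s = 0.34, T2s = 1e-5)
}

bloch_params <- function(T1f = 1.084, T2f = 0.065) {
  mt_params(m0s = 0, T1f = T1f, T2f = T2f, Tx = 0.05, T1s = 0.34,
            T2s = 1e-5)
}

random_params <- function() {
  mt_params(m0s = stats::runif(1, 0.05, 0.3),
            T1f = stats::runif(1, 1.2, 2.2),
            T2f = stats::runif(1, 0.04, 0.1),
            Tx = stats::runif(1, 0.02, 0.1),
            T1s = stats::runif(1, 0.2, 0.5),
            T2s = stats::runif(1, 5e-6, 1.5e-5))
}

# dense explicit ODE integration of the same linear system, independent of
# the matrix-exponential code path
ode_oracle <- function(G, s0, t) {
  out <- deSolve::lsoda(y = s0, times = c(0, t),
                        func = function(t, y, parms) list(as.vector(G %*% y)),
                        rtol = 1e-11, atol = 1e-13)
  as.numeric(out[2, -1])
}

# small deterministic suite for pipeline-level tests (fast: few measurements)
mini_suite <- function() {
  deg <- pi / 180
  list(
    vfa_protocol("mini_vfa", c(4, 18) * deg, 0.015, 1e-4),
    ir_protocol("mini_ir", c(0.1, 0.4, 1.2, 3), 8, inv_dur = 0.010),
    sr_protocol("mini_sr", c(0.2, 0.8, 2, 5), 7, sat_dur = 0, exc_dur = 1e-4),
    ll_protocol("mini_ll", 5 * deg, 0.3, 12, 8, delay1 = 0.1,
                inv_dur = 0.010, exc_dur = 1e-4)
  ) |> (\(x) stats::setNames(x, vapply(x, `[[`, "", "id")))()
}
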