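#' Two-pool magnetization-transfer parameter set
#'
#' Bundles the six tissue parameters of the two-pool MT model: the semi-solid
#' pool fraction `m0s` (with the normalization `m0f + m0s = 1`), the
#' longitudinal and transverse relaxation times of the free pool (`T1f`,
#' `T2f`), the inverse exchange rate `Tx`, and the longitudinal and transverse
#' relaxation times of the semi-solid pool (`T1s`, `T2s`). All times are in
#' seconds; `T2s` is of order 1e-5 s.
#'
#' `m0s` may be marginally negative (down to -0.05): the spin dynamics remain
#' linear and stable there, and finite-difference stencils centred on the
#' Bloch limit `m0s = 0` need that analytic continuation.
#'
#' @param m0s Semi-solid pool fraction, in (-0.05, 1).
#' @param T1f,T2f Free-pool relaxation times (s), strictly positive.
#' @param Tx Inverse exchange rate (s), strictly positive.
#' @param T1s,T2s Semi-solid relaxation times (s), strictly positive.
#' @return An object of class `mt_params` (a named list of the six values).
#' @examples
#' p <- mt_params(m0s = 0.2, T1f = 1.84, T2f = 0.065,
#'                Tx = 0.05, T1s = 0.34, T2s = 1e-5)
#' @export
mt_params <- function(m0s, T1f, T2f, Tx, T1s, T2s) {
  p <- list(m0s = m0s, T1f = T1f, T2f = T2f, Tx = Tx, T1s = T1s, T2s = T2s)
  vals <- unlist(p)
  if (!all(is.finite(vals))) {
    stop("all MT parameters must be finite numbers", call. = FALSE)
  }
  if (m0s <= -0.05 || m0s >= 1) {
    stop("m0s must lie in (-0.05, 1)", call. = FALSE)
  }
  for (nm in c("T1f", "T2f", "Tx", "T1s", "T2s")) {
    if (p[[nm]] <= 0) stop(nm, " must be strictly positive", call. = FALSE)
  }
  structure(p, class = "mt_params")
}

#' @export
print.mt_params <- function(x, ...) {
  cat("<mt_params>  m0s =", format(x$m0s),
      " T1f =", format(x$T1f), "s  T2f =", format(x$T2f), "s\n",
      "            Tx  =", format(x$Tx), "s  T1s =", format(x$T1s),
      "s  T2s =", format(x$T2s), "s\n")
  invisible(x)
}

#' Coerce a one-row data frame (or named list/vector) to `mt_params`
#'
#' Convenience for iterating over cohort tibbles: picks the six MT parameter
#' columns by name.
#'
#' @param x A named list, named numeric vector, or one-row data frame holding
#'   columns/entries `m0s, T1f, T2f, Tx, T1s, T2s`.
#' @return An `mt_params` object.
#' @export
as_mt_params <- function(x) {
  if (inherits(x, "mt_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- as.list(x)
  mt_params(m0s = as.numeric(x$m0s), T1f = as.numeric(x$T1f),
            T2f = as.numeric(x$T2f), Tx = as.numeric(x$Tx),
            T1s = as.numeric(x$T1s), T2s = as.numeric(x$T2s))
}

#' Thermal-equilibrium spin state
#'
#' The state vector ordering is `(xf, yf, zf, zs, 1)`: free-pool transverse
#' components, free-pool longitudinal, semi-solid longitudinal, and a
#' homogeneous constant component that turns affine dynamics (relaxation
#' toward equilibrium) into linear ones.
#'
#' @param p An [mt_params()] object.
#' @return Numeric vector of length 5: `c(0, 0, 1 - m0s, m0s, 1)`.
#' @export
equilibrium_state <- function(p) {
  c(0, 0, 1 - p$m0s, p$m0s, 1)
}

# Pade order-13 scaling-and-squaring matrix exponential (Higham 2005),
# specialised for the small dense generators used here. Hot path: called
# ~1e5 times per sensitivity run, so base-R only, no S4 dispatch.
expm_pade <- function(A) {
  nA <- max(colSums(abs(A)))
  j <- 0L
  if (nA > 5.371920351148152) {
    j <- as.integer(ceiling(log2(nA / 5.371920351148152)))
    A <- A / 2^j
  }
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  I <- diag(nrow(A))
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  E <- solve(V - U, V + U)
  if (j > 0L) for (k in seq_len(j)) E <- E %*% E
  E
}

new_propagator <- function(M, duration) {
  structure(M, duration = duration, class = c("mt_propagator", "matrix"))
}

#' @export
print.mt_propagator <- function(x, ...) {
  cat("<mt_propagator>  duration =", attr(x, "duration"), "s\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Relaxation--exchange generator of the two-pool MT model
#'
#' Returns the 5x5 affine generator `A` such that `d(state)/dt = A %*% state`
#' for a pulse-free interval, acting on the state ordering
#' `(xf, yf, zf, zs, 1)`:
#' \itemize{
#'   \item transverse decay `dxf/dt = -xf/T2f`, `dyf/dt = -yf/T2f`;
#'   \item `dzf/dt = (m0f - zf)/T1f - (m0s/Tx) zf + (m0f/Tx) zs`;
#'   \item `dzs/dt = (m0s - zs)/T1s + (m0s/Tx) zf - (m0f/Tx) zs`.
#' }
#' The exchange flux `(m0s/Tx) zf - (m0f/Tx) zs` is the detailed-balance form:
#' thermal equilibrium `(0, 0, m0f, m0s, 1)` is stationary for every `m0s`.
#' Recovery terms live in the homogeneous (fifth) column; the fifth row is
#' zero, so the homogeneous component is conserved.
#'
#' @param p An [mt_params()] object.
#' @return A 5x5 numeric generator matrix.
#' @export
relaxation_exchange_generator <- function(p) {
  m0f <- 1 - p$m0s
  A <- matrix(0, 5, 5)
  A[1, 1] <- -1 / p$T2f
  A[2, 2] <- -1 / p$T2f
  A[3, 3] <- -(1 / p$T1f + p$m0s / p$Tx)
  A[3, 4] <- m0f / p$Tx
  A[3, 5] <- m0f / p$T1f
  A[4, 3] <- p$m0s / p$Tx
  A[4, 4] <- -(1 / p$T1s + m0f / p$Tx)
  A[4, 5] <- p$m0s / p$T1s
  A
}

#' Free-evolution propagator
#'
#' Exact affine propagation of relaxation and exchange over an interval `dt`,
#' computed as the matrix exponential `expm(dt * A)` of the
#' relaxation--exchange generator (scaling-and-squaring, order-13 Pade).
#'
#' @param p An [mt_params()] object.
#' @param dt Interval duration in seconds, `dt >= 0`.
#' @return An `mt_propagator` (5x5 matrix with a `duration` attribute).
#' @export
free_propagator <- function(p, dt) {
  if (!is.finite(dt) || dt < 0) stop("dt must be >= 0", call. = FALSE)
  if (dt == 0) return(new_propagator(diag(5), 0))
  new_propagator(expm_pade(dt * relaxation_exchange_generator(p)), dt)
}

# --- absorption lineshapes -------------------------------------------------

# Value of the normalized absorption lineshape G(delta) in seconds.
# delta in Hz (offset from resonance), T2s in seconds.
lineshape_g <- function(delta, T2s,
                        lineshape = c("super_lorentzian", "lorentzian",
                                      "gaussian")) {
  lineshape <- match.arg(lineshape)
  switch(lineshape,
    lorentzian = (T2s / pi) / (1 + (2 * pi * delta * T2s)^2),
    gaussian = (T2s / sqrt(2 * pi)) * exp(-(2 * pi * delta * T2s)^2 / 2),
    super_lorentzian = vapply(delta, super_lorentzian_g, numeric(1),
                              T2s = T2s)
  )
}

# Super-Lorentzian lineshape by direct quadrature over the fibre-orientation
# variable u = cos(theta). Diverges at delta = 0; see super_lorentzian_g0().
super_lorentzian_g <- function(delta, T2s) {
  f <- function(u) {
    d <- abs(3 * u^2 - 1)
    out <- numeric(length(u))
    ok <- d > 1e-14
    out[ok] <- sqrt(2 / pi) / d[ok] *
      exp(-2 * (2 * pi * delta * T2s / d[ok])^2)
    out
  }
  T2s * stats::integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

# On-resonance super-Lorentzian value by quadratic interpolation of G(delta)
# from offsets >= `cutoff` down to delta = 0 (the standard convention for the
# integrable singularity of the on-resonance super-Lorentzian).
super_lorentzian_g0 <- function(T2s, cutoff = 1500) {
  d <- cutoff * c(1, 1.5, 2)
  g <- vapply(d, super_lorentzian_g, numeric(1), T2s = T2s)
  # quadratic through the three nodes, evaluated at delta = 0
  co <- solve(cbind(1, d, d^2), g)
  co[[1]]
}

#' RF saturation rate of the semi-solid pool
#'
#' The semi-solid pool's response to on-resonance RF irradiation is modeled as
#' an effective longitudinal saturation rate `R_rf = pi * omega1^2 * G(0)`,
#' with `G` the chosen absorption lineshape evaluated on resonance. This is
#' the linearized (steady-state) description of the semi-solid spin dynamics
#' during an RF pulse; the function is the designated swap-in point for more
#' elaborate semi-solid models.
#'
#' For the super-Lorentzian lineshape, whose on-resonance value diverges,
#' `G(0)` is obtained by quadratic interpolation of `G(delta)` from offsets
#' `>= cutoff` (default 1.5 kHz) down to zero.
#'
#' @param omega1 RF amplitude in rad/s, `>= 0`.
#' @param p An [mt_params()] object (only `T2s` is used).
#' @param lineshape One of `"super_lorentzian"` (default), `"lorentzian"`,
#'   `"gaussian"`.
#' @param cutoff Interpolation cutoff in Hz for the super-Lorentzian.
#' @return Saturation rate in 1/s.
#' @export
semisolid_saturation_rate <- function(omega1, p,
                                      lineshape = c("super_lorentzian",
                                                    "lorentzian", "gaussian"),
                                      cutoff = 1500) {
  lineshape <- match.arg(lineshape)
  if (any(omega1 < 0)) stop("omega1 must be >= 0", call. = FALSE)
  g0 <- switch(lineshape,
    lorentzian = p$T2s / pi,
    gaussian = p$T2s / sqrt(2 * pi),
    super_lorentzian = super_lorentzian_g0(p$T2s, cutoff = cutoff)
  )
  pi * omega1^2 * g0
}

# --- RF pulses -------------------------------------------------------------

#' RF pulse description
#'
#' A pulse is either `rectangular` (constant amplitude
#' `omega1 = flip/duration`) or `shaped` (amplitude `envelope(t)` in rad/s on
#' `[0, duration]`, with the unit-integral convention that the envelope
#' integrates to the flip angle). A `duration` of zero denotes an idealized
#' instantaneous rotation of the free pool that leaves the semi-solid pool
#' untouched.
#'
#' @param flip Flip angle in radians.
#' @param duration Pulse duration in seconds, `>= 0`.
#' @param phase RF phase in radians (axis of rotation in the transverse
#'   plane).
#' @param envelope For shaped pulses, a vectorized function of time returning
#'   omega1(t) in rad/s; its integral over `[0, duration]` must equal `flip`
#'   (checked to 1e-9 by quadrature).
#' @param sat_scale Scaling of the semi-solid saturation rate during this
#'   pulse (models, e.g., inversion pulses whose effective semi-solid
#'   saturation differs from the rectangular-pulse prediction).
#' @return An object of class `rf_pulse`.
#' @export
rf_pulse <- function(flip, duration, phase = 0, envelope = NULL,
                     sat_scale = 1) {
  if (!is.finite(duration) || duration < 0) {
    stop("duration must be >= 0", call. = FALSE)
  }
  kind <- if (is.null(envelope)) "rectangular" else "shaped"
  if (duration == 0) kind <- "instantaneous"
  if (kind == "shaped") {
    ig <- stats::integrate(envelope, 0, duration, rel.tol = 1e-12)$value
    if (abs(ig - flip) > 1e-9) {
      stop("shaped-pulse envelope must integrate to the flip angle ",
           "(got ", format(ig), ", expected ", format(flip), ")",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, flip = flip, duration = duration,
                 phase = phase, envelope = envelope, sat_scale = sat_scale),
            class = "rf_pulse")
}

# rotation generator about the transverse axis at `phase`, amplitude omega1
rotation_generator <- function(omega1, phase) {
  R <- matrix(0, 5, 5)
  R[1, 3] <- omega1 * sin(phase)
  R[3, 1] <- -omega1 * sin(phase)
  R[2, 3] <- -omega1 * cos(phase)
  R[3, 2] <- omega1 * cos(phase)
  R
}

#' Instantaneous rotation of the free pool
#'
#' Idealized zero-duration pulse: rotates `(xf, yf, zf)` by `flip` about the
#' transverse axis defined by `phase`; the semi-solid pool and the homogeneous
#' component are unchanged.
#'
#' @param flip Flip angle in radians.
#' @param phase Phase in radians.
#' @return An `mt_propagator` with duration 0.
#' @export
instantaneous_rotation <- function(flip, phase = 0) {
  u <- c(cos(phase), sin(phase), 0)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R3 <- diag(3) + sin(flip) * K + (1 - cos(flip)) * (K %*% K)
  M <- diag(5)
  M[1:3, 1:3] <- R3
  new_propagator(M, 0)
}

#' Propagator of a rectangular RF pulse
#'
#' Matrix exponential of `duration * (A + rotation + saturation)`: the free
#' pool nutates at constant `omega1 = flip/duration` about the phase-defined
#' axis, the semi-solid longitudinal component decays at the linearized
#' saturation rate [semisolid_saturation_rate()], and relaxation and exchange
#' stay active throughout the pulse.
#'
#' @param pulse An [rf_pulse()] with `kind = "rectangular"`.
#' @param p An [mt_params()] object.
#' @param lineshape Lineshape passed to [semisolid_saturation_rate()].
#' @return An `mt_propagator`.
#' @export
rect_pulse_propagator <- function(pulse, p,
                                  lineshape = "super_lorentzian") {
  if (pulse$kind != "rectangular") {
    stop("rect_pulse_propagator() needs a rectangular pulse with ",
         "duration > 0 (use instantaneous_rotation() for zero duration)",
         call. = FALSE)
  }
  omega1 <- pulse$flip / pulse$duration
  G <- relaxation_exchange_generator(p) +
    rotation_generator(omega1, pulse$phase)
  G[4, 4] <- G[4, 4] -
    pulse$sat_scale * semisolid_saturation_rate(abs(omega1), p, lineshape)
  new_propagator(expm_pade(pulse$duration * G), pulse$duration)
}

#' Propagator of a shaped RF pulse (classical RK4)
#'
#' Integrates the matrix ODE `dM/dt = G(t) M` with the classical 4th-order
#' Runge--Kutta method, where `G(t)` is the relaxation--exchange generator
#' plus the time-varying rotation term `omega1(t)` sampled from the envelope
#' and the corresponding instantaneous semi-solid saturation rate.
#'
#' @param pulse An [rf_pulse()] with `kind = "shaped"`.
#' @param p An [mt_params()] object.
#' @param n_steps Number of RK4 steps, `>= 4`.
#' @param lineshape Lineshape passed to [semisolid_saturation_rate()].
#' @return An `mt_propagator`.
#' @export
shaped_pulse_propagator <- function(pulse, p, n_steps = 100,
                                    lineshape = "super_lorentzian") {
  if (pulse$kind != "shaped") {
    stop("shaped_pulse_propagator() needs a shaped pulse", call. = FALSE)
  }
  if (n_steps < 4) stop("n_steps must be >= 4", call. = FALSE)
  A <- relaxation_exchange_generator(p)
  g0 <- semisolid_saturation_rate(1, p, lineshape)  # rate per omega1^2
  gen_at <- function(t) {
    w <- pulse$envelope(t)
    if (!is.finite(w)) {
      stop("pulse envelope is not finite at t = ", format(t), call. = FALSE)
    }
    G <- A + rotation_generator(w, pulse$phase)
    G[4, 4] <- G[4, 4] - pulse$sat_scale * g0 * w^2
    G
  }
  h <- pulse$duration / n_steps
  M <- diag(5)
  for (i in seq_len(n_steps)) {
    t0 <- (i - 1) * h
    k1 <- gen_at(t0) %*% M
    k2 <- gen_at(t0 + h / 2) %*% (M + h / 2 * k1)
    k3 <- gen_at(t0 + h / 2) %*% (M + h / 2 * k2)
    k4 <- gen_at(t0 + h) %*% (M + h * k3)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  new_propagator(M, pulse$duration)
}

#' Composite (adiabatic-like) inversion propagator
#'
#' Idealizes a frequency-swept inversion pulse: the free pool is inverted
#' exactly (instantaneous pi rotation, as adiabatic passage is insensitive to
#' B1 and leaves no transverse residue), while the semi-solid longitudinal
#' component is attenuated by `exp(-sat_scale * R_rf * duration)` with
#' `R_rf` evaluated at the nominal RF amplitude `omega1 = pi / duration`.
#' This separates the two experimentally distinct actions of an inversion
#' pulse on the two pools: near-perfect inversion of the liquid pool and
#' partial saturation of the macromolecular pool, the latter being a key
#' mechanism of MT sensitivity in inversion-based T1 mapping.
#'
#' @param p An [mt_params()] object.
#' @param duration Nominal pulse duration (s) setting the RF power.
#' @param sat_scale Semi-solid saturation efficiency scaling.
#' @param lineshape Lineshape passed to [semisolid_saturation_rate()].
#' @return An `mt_propagator` with duration 0 (the timing diagram treats the
#'   pulse as acting at its centre).
#' @export
composite_inversion <- function(p, duration = 0.010, sat_scale = 1,
                                lineshape = "super_lorentzian") {
  omega1 <- pi / duration
  M <- unclass(instantaneous_rotation(pi, 0))
  M[4, 4] <- exp(-sat_scale * duration *
                   semisolid_saturation_rate(omega1, p, lineshape))
  new_propagator(M, 0)
}

# propagator for any rf_pulse object
pulse_propagator <- function(pulse, p, lineshape = "super_lorentzian",
                             n_steps = 100) {
  switch(pulse$kind,
    instantaneous = instantaneous_rotation(pulse$flip, pulse$phase),
    rectangular = rect_pulse_propagator(pulse, p, lineshape),
    shaped = shaped_pulse_propagator(pulse, p, n_steps, lineshape)
  )
}

#' Complete spoiling
#'
#' Sets the free-pool transverse components to zero (idealized crusher /
#' RF spoiling); longitudinal components are untouched. Idempotent.
#'
#' @param state A length-5 spin-state vector.
#' @return The spoiled state vector.
#' @export
spoil <- function(state) {
  state[1] <- 0
  state[2] <- 0
  state
}

# spoiling as a propagator matrix (for composing cycles)
spoil_matrix <- function() {
  diag(c(0, 0, 1, 1, 1))
}
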