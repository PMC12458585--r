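new_fit <- function(T1o, scale, aux, converged, rms, type) {
  structure(list(T1o = T1o, scale = scale, aux = aux,
                 converged = converged, rms_residual = rms, type = type),
            class = "t1_fit")
}

failed_fit <- function(type, aux = list()) {
  new_fit(NA_real_, NA_real_, aux, FALSE, NA_real_, type)
}

#' @export
print.t1_fit <- function(x, ...) {
  cat("<t1_fit>", x$type, " T1o =", format(x$T1o), "s  converged =",
      x$converged, " rms =", format(x$rms_residual), "\n")
  invisible(x)
}

#' @rdname t1sens-tidiers
#' @export
tidy.t1_fit <- function(x, ...) {
  tibble::tibble(term = c("T1o", "scale"),
                 estimate = c(x$T1o, x$scale))
}

#' @rdname t1sens-tidiers
#' @export
glance.t1_fit <- function(x, ...) {
  tibble::tibble(T1o = x$T1o, converged = x$converged,
                 rms_residual = x$rms_residual, type = x$type)
}

lm_control <- function() {
  minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15,
                             gtol = 0)
}

rms <- function(r) sqrt(mean(r^2))

#' Three-parameter inversion-recovery fit
#'
#' Nonlinear least squares of `S(TI) = A + B * exp(-TI / T1o)` over
#' `(A, B, T1o)` on signed (phase-corrected) signals. Deterministic
#' initialization: `A0 = S(TI_max)`, `B0 = S(TI_min) - S(TI_max)`, and `T10`
#' from the zero-crossing TI divided by `log(2)` when a sign change exists,
#' else the median TI.
#'
#' @param s A signal tibble with columns `abscissa` (TI, s) and `value`.
#' @return A `t1_fit` with `T1o`, the fitted scale `|B|`, nuisance
#'   parameters, a convergence flag, and the RMS residual.
#' @export
fit_inversion_recovery <- function(s) {
  TI <- s$abscissa
  y <- s$value
  if (length(TI) < 3) stop("need >= 3 TI samples", call. = FALSE)
  A0 <- y[which.max(TI)]
  B0 <- y[which.min(TI)] - A0
  sgn <- sign(y)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross) > 0) {
    i <- cross[1]
    tc <- TI[i] + (TI[i + 1] - TI[i]) * abs(y[i]) / (abs(y[i]) + abs(y[i + 1]))
    T10 <- tc / log(2)
  } else {
    T10 <- stats::median(TI)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + B * exp(-TI / T1),
                      start = list(A = A0, B = B0, T1 = T10),
                      control = lm_control()),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit("inversion_recovery"))
  co <- stats::coef(fit)
  conv <- is.finite(co[["T1"]]) && co[["T1"]] > 0
  new_fit(if (conv) co[["T1"]] else NA_real_, abs(co[["B"]]),
          list(A = co[["A"]], B = co[["B"]]), conv,
          rms(stats::residuals(fit)), "inversion_recovery")
}

#' Two-parameter saturation-recovery fit
#'
#' Least squares of `S(TS) = A * (1 - exp(-TS / T1o))`.
#'
#' @param s A signal tibble with columns `abscissa` (TS, s) and `value`.
#' @return A `t1_fit`.
#' @export
fit_saturation_recovery <- function(s) {
  TS <- s$abscissa
  y <- s$value
  if (length(TS) < 2) stop("need >= 2 TS samples", call. = FALSE)
  A0 <- max(abs(y)) * sign(y[which.max(TS)])
  T10 <- stats::median(TS)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-TS / T1)),
                      start = list(A = A0, T1 = T10),
                      control = lm_control()),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit("saturation_recovery"))
  co <- stats::coef(fit)
  conv <- is.finite(co[["T1"]]) && co[["T1"]] > 0
  new_fit(if (conv) co[["T1"]] else NA_real_, co[["A"]],
          list(A = co[["A"]]), conv, rms(stats::residuals(fit)),
          "saturation_recovery")
}

#' Look-Locker fit with apparent-T1 correction
#'
#' Fits the apparent recovery `S(t) = A - B * exp(-t / T1star)` along the
#' readout train, then converts the apparent T1star to T1o with one of two
#' published correction styles:
#' \itemize{
#'   \item `"ratio"`: the classic amplitude-ratio correction
#'     `T1o = T1star * (B/A - 1)`, which assumes perfect inversion and
#'     sampling from the inversion onward; results with `B/A <= 1` are
#'     flagged as non-converged.
#'   \item `"flip_angle"`: the rate correction
#'     `1/T1o = 1/T1star + log(cos(flip))/spacing`, using the known readout
#'     flip angle and spacing. Only the recovery rate enters, so this
#'     variant is insensitive to inversion efficiency and the initial delay
#'     and is exact under the mono-exponential signal model with idealized
#'     readout pulses.
#' }
#'
#' @param s A signal tibble with `abscissa` = readout time after inversion (s)
#'   and `value` = signed readout signal.
#' @param correction Correction style (see above).
#' @param flip,spacing Readout flip (rad) and spacing (s), required for the
#'   `"flip_angle"` correction.
#' @return A `t1_fit`; `aux` carries `A`, `B`, and `T1star`.
#' @export
fit_look_locker <- function(s, correction = c("ratio", "flip_angle"),
                            flip = NULL, spacing = NULL) {
  correction <- match.arg(correction)
  if (correction == "flip_angle" && (is.null(flip) || is.null(spacing))) {
    stop("flip and spacing required for the flip-angle correction",
         call. = FALSE)
  }
  t <- s$abscissa
  y <- s$value
  if (length(t) < 3) stop("need >= 3 readouts", call. = FALSE)
  A0 <- y[which.max(t)]
  B0 <- A0 - y[which.min(t)]
  sgn <- sign(y)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  T10 <- if (length(cross) > 0) t[cross[1]] / log(2) else stats::median(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A - B * exp(-t / T1s_),
                      start = list(A = A0, B = B0, T1s_ = T10),
                      control = lm_control()),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit("look_locker"))
  co <- stats::coef(fit)
  if (correction == "ratio") {
    ratio <- co[["B"]] / co[["A"]]
    conv <- is.finite(ratio) && ratio > 1 && co[["T1s_"]] > 0
    T1o <- if (conv) co[["T1s_"]] * (ratio - 1) else NA_real_
  } else {
    inv_T1 <- 1 / co[["T1s_"]] + log(cos(flip)) / spacing
    conv <- is.finite(inv_T1) && inv_T1 > 0 && co[["T1s_"]] > 0
    T1o <- if (conv) 1 / inv_T1 else NA_real_
  }
  new_fit(T1o, co[["B"]],
          list(A = co[["A"]], B = co[["B"]], T1star = co[["T1s_"]]),
          conv, rms(stats::residuals(fit)), "look_locker")
}

#' DESPOT1 variable-flip-angle fit
#'
#' Linearizes the spoiled steady-state (Ernst) equation: regresses
#' `S/sin(alpha)` on `S/tan(alpha)`; the slope `m = exp(-TR/T1o)` gives
#' `T1o = -TR / log(m)`, and the intercept absorbs the overall scale. Slopes
#' outside `(0, 1)` are flagged.
#'
#' @param s A signal tibble with `abscissa` = flip angle (rad) and `value`;
#'   `TR` may be carried as an attribute.
#' @param TR Repetition time (s); defaults to the `TR` attribute of `s`.
#' @return A `t1_fit`; `aux` carries the regression slope and intercept.
#' @export
fit_vfa_despot1 <- function(s, TR = attr(s, "TR")) {
  if (is.null(TR)) stop("TR must be supplied for the VFA fit", call. = FALSE)
  a <- s$abscissa
  y <- s$value
  if (length(unique(a)) < 2) stop("need >= 2 distinct flips", call. = FALSE)
  fit <- stats::lm(I(y / sin(a)) ~ I(y / tan(a)))
  m <- stats::coef(fit)[[2]]
  b <- stats::coef(fit)[[1]]
  conv <- is.finite(m) && m > 0 && m < 1
  T1o <- if (conv) -TR / log(m) else NA_real_
  scale <- if (conv) b / (1 - m) else NA_real_
  new_fit(T1o, scale, list(slope = m, intercept = b), conv,
          rms(stats::residuals(fit)), "variable_flip_angle")
}

# --- MP2RAGE lookup --------------------------------------------------------

.lookup_cache <- new.env(parent = emptyenv())

lookup_key <- function(protocol) {
  paste(protocol$id, protocol$TI1, protocol$TI2,
        paste(protocol$flips, collapse = ","), protocol$spacing,
        protocol$n_per_block, protocol$TR, protocol$inv_dur,
        protocol$exc_dur, protocol$inv_model, sep = "|")
}

# maximal strictly monotone run of U containing the grid midpoint; the
# ratio-T1 curve folds at extreme T1 for some timings, and only the central
# monotone branch is invertible
monotone_branch <- function(T1, U) {
  s <- sign(diff(U))
  mid <- floor(length(U) / 2)
  dir <- s[mid]
  if (dir == 0) return(list(T1 = T1[mid], U = U[mid]))
  lo <- mid
  while (lo > 1 && s[lo - 1] == dir) lo <- lo - 1
  hi <- mid
  while (hi < length(s) && s[hi + 1] == dir) hi <- hi + 1
  idx <- lo:(hi + 1)
  list(T1 = T1[idx], U = U[idx])
}

#' MP2RAGE calibration lookup
#'
#' Builds (and caches) the monotone mapping from the bias-normalized ratio
#' `U = S1 * S2 / (S1^2 + S2^2)` to T1 by simulating the identical protocol
#' under the mono-exponential (Bloch) model, i.e. `m0s = 0`, over a T1 grid.
#' Calibrating on the Bloch model is deliberate: magnetization-transfer
#' effects then appear as bias in the observed T1, which is exactly the
#' quantity under study.
#'
#' @param protocol An `mp2rage` `t1_protocol`.
#' @param T1_grid Calibration grid (s); default 0.1 to 5 s at 1 ms spacing.
#' @param T2f_cal Nominal free-pool T2 used during calibration (s); it only
#'   enters through relaxation during the ~1 ms pulses.
#' @return A list with `T1`, `U`, and the monotone direction, for use by
#'   [fit_mp2rage()].
#' @export
mp2rage_lookup <- function(protocol, T1_grid = seq(0.1, 5, by = 0.001),
                           T2f_cal = 0.065) {
  key <- lookup_key(protocol)
  if (!is.null(.lookup_cache[[key]])) return(.lookup_cache[[key]])
  U <- vapply(T1_grid, function(T1) {
    p <- mt_params(m0s = 0, T1f = T1, T2f = T2f_cal, Tx = 0.05,
                   T1s = 0.34, T2s = 1e-5)
    s <- simulate_signals(protocol, p)
    s1 <- s$value[1]
    s2 <- s$value[2]
    s1 * s2 / (s1^2 + s2^2)
  }, numeric(1))
  br <- monotone_branch(T1_grid, U)
  lk <- list(T1 = br$T1, U = br$U, monotone = length(br$T1) > 1,
             increasing = length(br$T1) > 1 && br$U[2] > br$U[1])
  .lookup_cache[[key]] <- lk
  lk
}

#' MP2RAGE T1 estimation via the uniform-image ratio
#'
#' Forms `U = S1 * S2 / (S1^2 + S2^2)` from the two block signals (invariant
#' under a common rescaling of both signals) and inverts it through the
#' Bloch-model calibration lookup of the same protocol, with linear
#' interpolation. Ratios outside the lookup's monotone range are flagged.
#'
#' @param s A signal tibble with two rows (block 1 and block 2 signals).
#' @param protocol The `mp2rage` `t1_protocol` that produced `s`; defaults to
#'   the protocol carried on `s`.
#' @param lookup Optional precomputed [mp2rage_lookup()].
#' @return A `t1_fit`; `aux` carries `U`.
#' @export
fit_mp2rage <- function(s, protocol = attr(s, "protocol"), lookup = NULL) {
  if (is.null(protocol)) stop("protocol required for MP2RAGE fit", call. = FALSE)
  if (nrow(s) != 2) stop("MP2RAGE fit needs exactly 2 block signals",
                         call. = FALSE)
  s1 <- s$value[1]
  s2 <- s$value[2]
  U <- s1 * s2 / (s1^2 + s2^2)
  lk <- lookup %||% mp2rage_lookup(protocol)
  if (!lk$monotone) return(failed_fit("mp2rage", aux = list(U = U)))
  rng <- range(lk$U)
  if (U < rng[1] || U > rng[2]) {
    return(failed_fit("mp2rage", aux = list(U = U)))
  }
  xs <- lk$U
  ys <- lk$T1
  if (!lk$increasing) {       # approx() needs ascending x
    xs <- rev(xs)
    ys <- rev(ys)
  }
  T1o <- stats::approx(xs, ys, xout = U, ties = "ordered")$y
  new_fit(T1o, sqrt(s1^2 + s2^2), list(U = U), TRUE, 0, "mp2rage")
}

#' Fit the observed T1 with a protocol's native procedure
#'
#' Dispatches a simulated [simulate_signals()] set to the fitting procedure
#' matching the sequence type: three-parameter IR, two-parameter SR,
#' Look-Locker with apparent-T1 correction, DESPOT1 linearization, or the
#' MP2RAGE ratio lookup. The overall signal scale is always fitted (or, for
#' MP2RAGE, cancelled by the ratio), never assumed.
#'
#' @param s A signal tibble from [simulate_signals()].
#' @param protocol The protocol that produced `s`; defaults to the attribute.
#' @return A `t1_fit`.
#' @export
fit_t1 <- function(s, protocol = attr(s, "protocol")) {
  if (is.null(protocol)) stop("protocol required", call. = FALSE)
  switch(protocol$type,
    inversion_recovery = fit_inversion_recovery(s),
    saturation_recovery = fit_saturation_recovery(s),
    look_locker = fit_look_locker(s,
      correction = protocol$ll_correction %||% "ratio",
      flip = protocol$readout_flip, spacing = protocol$spacing),
    variable_flip_angle = fit_vfa_despot1(s, TR = protocol$TR),
    mp2rage = fit_mp2rage(s, protocol)
  )
}

#' Simulate a protocol and fit its observed T1
#'
#' Convenience wrapper: [simulate_signals()] followed by [fit_t1()]. This is
#' the scalar map from the six MT parameters to the observed T1 that the
#' sensitivity analysis differentiates.
#'
#' @inheritParams simulate_signals
#' @return A `t1_fit`.
#' @export
observed_t1 <- function(protocol, p, lineshape = "super_lorentzian",
                        tol = 1e-9) {
  fit_t1(simulate_signals(protocol, p, lineshape = lineshape, tol = tol),
         protocol)
}
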