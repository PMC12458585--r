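#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

new_protocol <- function(type, id, fields) {
  structure(c(list(id = id, type = type), fields), class = "t1_protocol")
}

#' @export
print.t1_protocol <- function(x, ...) {
  cat("<t1_protocol>", x$id, " type =", x$type, "\n")
  utils::str(x[setdiff(names(x), c("id", "type"))], give.attr = FALSE)
  invisible(x)
}

stop_protocol <- function(id, field, msg) {
  stop("protocol '", id, "', field '", field, "': ", msg, call. = FALSE)
}

#' Inversion-recovery protocol
#'
#' @param id Unique protocol id.
#' @param TI Strictly increasing vector of inversion times (s), length >= 3,
#'   measured centre-of-inversion to centre-of-excitation.
#' @param TR Repetition time (s), inversion to inversion.
#' @param inv_dur Inversion-pulse duration (s); 0 means an idealized
#'   instantaneous pi pulse.
#' @param exc_dur Excitation-pulse duration (s); 0 means instantaneous.
#' @param exc_flip Excitation flip angle (rad).
#' @param inv_sat_scale Scaling of the semi-solid saturation rate during the
#'   inversion pulse (semi-solid inversion efficiency knob).
#' @param inv_model Inversion-pulse model: `"rect"` (finite rectangular pi
#'   pulse, matrix exponential) or `"composite"` (adiabatic-like: exact
#'   free-pool inversion plus semi-solid saturation at the nominal RF power,
#'   see [composite_inversion()]).
#' @return A `t1_protocol` of type `"inversion_recovery"`.
#' @export
ir_protocol <- function(id, TI, TR, inv_dur = 0.010, exc_dur = 0.001,
                        exc_flip = pi / 2, inv_sat_scale = 1,
                        inv_model = c("rect", "composite")) {
  inv_model <- match.arg(inv_model)
  if (length(TI) < 3) stop_protocol(id, "TI", "needs >= 3 inversion times")
  if (any(diff(TI) <= 0)) stop_protocol(id, "TI", "must be strictly increasing")
  if (any(TI <= 0) || TR <= 0) stop_protocol(id, "TI/TR", "must be positive")
  if (max(TI) >= TR) stop_protocol(id, "TR", "must exceed max(TI)")
  new_protocol("inversion_recovery", id,
               list(TI = TI, TR = TR, inv_dur = inv_dur, exc_dur = exc_dur,
                    exc_flip = exc_flip, inv_sat_scale = inv_sat_scale,
                    inv_model = inv_model))
}

#' Saturation-recovery protocol
#'
#' Saturation is modeled as a 90-degree pulse followed by complete spoiling.
#'
#' @inheritParams ir_protocol
#' @param TS Strictly increasing vector of saturation-recovery times (s),
#'   length >= 3.
#' @param sat_dur Saturation-pulse duration (s); 0 means instantaneous.
#' @return A `t1_protocol` of type `"saturation_recovery"`.
#' @export
sr_protocol <- function(id, TS, TR, sat_dur = 0.001, exc_dur = 0.001,
                        exc_flip = pi / 2) {
  if (length(TS) < 3) stop_protocol(id, "TS", "needs >= 3 recovery times")
  if (any(diff(TS) <= 0)) stop_protocol(id, "TS", "must be strictly increasing")
  if (any(TS <= 0) || TR <= 0) stop_protocol(id, "TS/TR", "must be positive")
  if (max(TS) >= TR) stop_protocol(id, "TR", "must exceed max(TS)")
  new_protocol("saturation_recovery", id,
               list(TS = TS, TR = TR, sat_dur = sat_dur, exc_dur = exc_dur,
                    exc_flip = exc_flip))
}

#' Variable-flip-angle (spoiled gradient echo) protocol
#'
#' @inheritParams ir_protocol
#' @param flips Vector of >= 2 distinct excitation flip angles (rad).
#' @param TR Repetition time (s).
#' @return A `t1_protocol` of type `"variable_flip_angle"`.
#' @export
vfa_protocol <- function(id, flips, TR, exc_dur = 0.001) {
  if (length(unique(flips)) < 2) {
    stop_protocol(id, "flips", "needs >= 2 distinct flip angles")
  }
  if (any(flips <= 0) || TR <= 0) stop_protocol(id, "flips/TR", "must be positive")
  new_protocol("variable_flip_angle", id,
               list(flips = flips, TR = TR, exc_dur = exc_dur))
}

#' Look-Locker protocol
#'
#' Inversion followed by a train of small-flip spoiled readouts during
#' recovery; readout `k` sits at `delay1 + (k - 1) * spacing` after the
#' inversion centre.
#'
#' @inheritParams ir_protocol
#' @param readout_flip Readout flip angle (rad).
#' @param spacing Readout spacing (s).
#' @param n_readouts Number of readouts per inversion, >= 3.
#' @param delay1 Inversion centre to first readout centre (s).
#' @param ll_correction Apparent-T1 correction variant used by the native
#'   fitter: `"flip_angle"` (rate correction from the known readout flip,
#'   exact under the mono-exponential model) or `"ratio"` (the classic
#'   `T1 = T1star * (B/A - 1)` amplitude-ratio correction).
#' @return A `t1_protocol` of type `"look_locker"`.
#' @export
ll_protocol <- function(id, readout_flip, spacing, n_readouts, TR,
                        delay1 = 0.1, inv_dur = 0.010, exc_dur = 0.001,
                        inv_sat_scale = 1,
                        inv_model = c("composite", "rect"),
                        ll_correction = c("flip_angle", "ratio")) {
  inv_model <- match.arg(inv_model)
  ll_correction <- match.arg(ll_correction)
  if (n_readouts < 3) stop_protocol(id, "n_readouts", "needs >= 3 readouts")
  if (any(c(readout_flip, spacing, TR, delay1) <= 0)) {
    stop_protocol(id, "timing", "must be positive")
  }
  if (delay1 + n_readouts * spacing >= TR) {
    stop_protocol(id, "TR", "readout train must fit inside TR")
  }
  new_protocol("look_locker", id,
               list(readout_flip = readout_flip, spacing = spacing,
                    n_readouts = n_readouts, TR = TR, delay1 = delay1,
                    inv_dur = inv_dur, exc_dur = exc_dur,
                    inv_sat_scale = inv_sat_scale, inv_model = inv_model,
                    ll_correction = ll_correction))
}

#' MP2RAGE protocol
#'
#' Two spoiled gradient-echo blocks after an inversion; `TI1`/`TI2` locate
#' the centre readout of each block relative to the inversion centre. T1 is
#' later estimated from the bias-normalized ratio of the two block signals.
#'
#' @inheritParams ir_protocol
#' @param TI1,TI2 Inversion times of the two block centres (s), `TI1 < TI2`.
#' @param flips Length-2 vector of block excitation flips (rad).
#' @param spacing Readout spacing inside a block (s).
#' @param n_per_block Readouts per block, >= 2.
#' @return A `t1_protocol` of type `"mp2rage"`.
#' @export
mp2rage_protocol <- function(id, TI1, TI2, flips, spacing, n_per_block, TR,
                             inv_dur = 0.010, exc_dur = 0.001,
                             inv_sat_scale = 1,
                             inv_model = c("composite", "rect")) {
  inv_model <- match.arg(inv_model)
  if (length(flips) != 2) stop_protocol(id, "flips", "needs exactly 2 flips")
  if (n_per_block < 2) stop_protocol(id, "n_per_block", "needs >= 2 readouts")
  if (any(c(TI1, TI2, flips, spacing, TR) <= 0)) {
    stop_protocol(id, "timing", "must be positive")
  }
  if (TI2 <= TI1) stop_protocol(id, "TI2", "must exceed TI1")
  if (TI2 - TI1 < n_per_block * spacing) {
    stop_protocol(id, "TI2", "blocks must not overlap")
  }
  if (TI2 + n_per_block * spacing >= TR) {
    stop_protocol(id, "TR", "second block must fit inside TR")
  }
  new_protocol("mp2rage", id,
               list(TI1 = TI1, TI2 = TI2, flips = flips, spacing = spacing,
                    n_per_block = n_per_block, TR = TR, inv_dur = inv_dur,
                    exc_dur = exc_dur, inv_sat_scale = inv_sat_scale,
                    inv_model = inv_model))
}

# pulse helpers: duration 0 -> instantaneous idealization
make_pulse <- function(flip, duration, sat_scale = 1) {
  rf_pulse(flip = flip, duration = duration, sat_scale = sat_scale)
}

# inversion propagator + the time it occupies in the timing diagram
# (composite inversions act at their centre, so they occupy no time)
inversion_prop <- function(pr, p, lineshape) {
  if (identical(pr$inv_model, "composite") && pr$inv_dur > 0) {
    list(P = composite_inversion(p, pr$inv_dur, pr$inv_sat_scale, lineshape),
         tdur = 0)
  } else {
    list(P = pulse_propagator(make_pulse(pi, pr$inv_dur, pr$inv_sat_scale),
                              p, lineshape),
         tdur = pr$inv_dur)
  }
}

# --- cycle machinery -------------------------------------------------------

# A cycle is a list whose elements are 5x5 propagator matrices or the string
# "readout". steady_state() finds the periodic pre-cycle state by
# cycle-doubling: repeatedly squaring the full-cycle propagator until the
# state it produces changes by < tol in max-norm (equivalent to running
# 2^k cycles).
steady_state <- function(C, s0, tol = 1e-9, max_doublings = 60,
                         protocol_id = "?") {
  s <- s0
  for (k in seq_len(max_doublings)) {
    s_new <- as.vector(C %*% s)
    if (max(abs(s_new - s)) < tol) return(s_new)
    s <- s_new
    C <- C %*% C
  }
  stop("steady-state iteration did not converge for protocol '",
       protocol_id, "'", call. = FALSE)
}

cycle_matrix <- function(ops) {
  C <- diag(5)
  for (op in ops) if (!is.character(op)) C <- op %*% C
  C
}

# run one cycle from state s, collecting the signed free-pool transverse
# signal (-yf, i.e. the component along the readout axis for phase-0
# excitation) at each "readout" marker
run_cycle <- function(ops, s) {
  signals <- numeric(0)
  for (op in ops) {
    if (is.character(op)) {
      signals <- c(signals, -s[2])
    } else {
      s <- as.vector(op %*% s)
    }
  }
  list(signals = signals, state = s)
}

simulate_cycle <- function(ops, p, tol, protocol_id) {
  C <- cycle_matrix(ops)
  s0 <- steady_state(C, equilibrium_state(p), tol = tol,
                     protocol_id = protocol_id)
  run_cycle(ops, s0)$signals
}

new_signal_set <- function(protocol, abscissa, values) {
  sig <- tibble(protocol_id = protocol$id, abscissa = abscissa,
                value = values)
  attr(sig, "seq_type") <- protocol$type
  attr(sig, "protocol") <- protocol
  sig
}

#' Simulate the measured signals of a T1-mapping protocol
#'
#' Composes the two-pool MT propagators of the protocol's pulse-timing
#' diagram (pulse, free evolution, complete spoiling per repetition),
#' establishes the periodic steady state of each repeating cycle, and records
#' the signed free-pool transverse magnetization immediately after each
#' readout excitation.
#'
#' @param protocol A `t1_protocol`.
#' @param p An [mt_params()] object.
#' @param lineshape Semi-solid absorption lineshape (see
#'   [semisolid_saturation_rate()]).
#' @param tol Steady-state tolerance on the state vector (max-norm).
#' @return A tibble with columns `protocol_id`, `abscissa` (TI, TS, flip
#'   angle, readout time, or block index, per sequence type), and `value`;
#'   the protocol and its type are carried as attributes.
#' @export
simulate_signals <- function(protocol, p, lineshape = "super_lorentzian",
                             tol = 1e-9) {
  stopifnot(inherits(protocol, "t1_protocol"))
  p <- as_mt_params(p)
  switch(protocol$type,
    inversion_recovery = simulate_ir(protocol, p, lineshape, tol),
    saturation_recovery = simulate_sr(protocol, p, lineshape, tol),
    variable_flip_angle = simulate_vfa(protocol, p, lineshape, tol),
    look_locker = simulate_ll(protocol, p, lineshape, tol),
    mp2rage = simulate_mp2rage(protocol, p, lineshape, tol)
  )
}

simulate_ir <- function(pr, p, lineshape, tol) {
  inv <- inversion_prop(pr, p, lineshape)
  P_inv <- inv$P
  P_exc <- pulse_propagator(make_pulse(pr$exc_flip, pr$exc_dur), p, lineshape)
  S <- spoil_matrix()
  half <- inv$tdur / 2 + pr$exc_dur / 2
  vals <- vapply(pr$TI, function(TI) {
    gap1 <- TI - half
    rec <- pr$TR - TI - half
    if (gap1 <= 0 || rec <= 0) {
      stop_protocol(pr$id, "TI", "pulses overlap for this TI/TR")
    }
    ops <- list(P_inv, S, free_propagator(p, gap1), P_exc, "readout", S,
                free_propagator(p, rec))
    simulate_cycle(ops, p, tol, pr$id)
  }, numeric(1))
  new_signal_set(pr, pr$TI, vals)
}

simulate_sr <- function(pr, p, lineshape, tol) {
  P_sat <- pulse_propagator(make_pulse(pi / 2, pr$sat_dur), p, lineshape)
  P_exc <- pulse_propagator(make_pulse(pr$exc_flip, pr$exc_dur), p, lineshape)
  S <- spoil_matrix()
  half <- pr$sat_dur / 2 + pr$exc_dur / 2
  vals <- vapply(pr$TS, function(TS) {
    gap1 <- TS - half
    rec <- pr$TR - TS - half
    if (gap1 <= 0 || rec <= 0) {
      stop_protocol(pr$id, "TS", "pulses overlap for this TS/TR")
    }
    ops <- list(P_sat, S, free_propagator(p, gap1), P_exc, "readout", S,
                free_propagator(p, rec))
    simulate_cycle(ops, p, tol, pr$id)
  }, numeric(1))
  new_signal_set(pr, pr$TS, vals)
}

simulate_vfa <- function(pr, p, lineshape, tol) {
  S <- spoil_matrix()
  P_fill <- free_propagator(p, pr$TR - pr$exc_dur)
  vals <- vapply(pr$flips, function(a) {
    P_exc <- pulse_propagator(make_pulse(a, pr$exc_dur), p, lineshape)
    ops <- list(P_exc, "readout", S, P_fill)
    simulate_cycle(ops, p, tol, pr$id)
  }, numeric(1))
  sig <- new_signal_set(pr, pr$flips, vals)
  attr(sig, "TR") <- pr$TR
  sig
}

simulate_ll <- function(pr, p, lineshape, tol) {
  inv <- inversion_prop(pr, p, lineshape)
  P_inv <- inv$P
  P_exc <- pulse_propagator(make_pulse(pr$readout_flip, pr$exc_dur),
                            p, lineshape)
  S <- spoil_matrix()
  gap1 <- pr$delay1 - inv$tdur / 2 - pr$exc_dur / 2
  if (gap1 <= 0) stop_protocol(pr$id, "delay1", "inversion overlaps readout")
  P_space <- free_propagator(p, pr$spacing - pr$exc_dur)
  tail <- pr$TR - inv$tdur / 2 - gap1 - pr$n_readouts * pr$spacing -
    pr$exc_dur / 2
  if (tail <= 0) stop_protocol(pr$id, "TR", "readout train exceeds TR")
  ops <- c(list(P_inv, S, free_propagator(p, gap1)),
           rep(list(P_exc, "readout", S, P_space), pr$n_readouts),
           list(free_propagator(p, tail)))
  vals <- simulate_cycle(ops, p, tol, pr$id)
  t_k <- pr$delay1 + (seq_len(pr$n_readouts) - 1) * pr$spacing
  new_signal_set(pr, t_k, vals)
}

simulate_mp2rage <- function(pr, p, lineshape, tol) {
  inv <- inversion_prop(pr, p, lineshape)
  P_inv <- inv$P
  P_exc1 <- pulse_propagator(make_pulse(pr$flips[1], pr$exc_dur), p, lineshape)
  P_exc2 <- pulse_propagator(make_pulse(pr$flips[2], pr$exc_dur), p, lineshape)
  S <- spoil_matrix()
  n <- pr$n_per_block
  ic <- floor((n + 1) / 2)                # centre readout index
  P_space <- free_propagator(p, pr$spacing - pr$exc_dur)
  tA <- pr$TI1 - (ic - 1) * pr$spacing    # first readout centre, block 1
  tB <- pr$TI2 - (ic - 1) * pr$spacing
  gapA <- tA - inv$tdur / 2 - pr$exc_dur / 2
  gapB <- tB - (tA + n * pr$spacing)
  tail <- pr$TR - inv$tdur / 2 - gapA - 2 * n * pr$spacing - gapB -
    pr$exc_dur / 2
  if (gapA <= 0 || gapB <= 0 || tail <= 0) {
    stop_protocol(pr$id, "TI1/TI2/TR", "blocks do not fit the cycle")
  }
  ops <- c(list(P_inv, S, free_propagator(p, gapA)),
           rep(list(P_exc1, "readout", S, P_space), n),
           list(free_propagator(p, gapB)),
           rep(list(P_exc2, "readout", S, P_space), n),
           list(free_propagator(p, tail)))
  vals <- simulate_cycle(ops, p, tol, pr$id)
  new_signal_set(pr, c(1, 2), c(vals[ic], vals[n + ic]))
}

# --- default suite ---------------------------------------------------------

#' Default T1-mapping protocol suite
#'
#' A deterministic, representative suite of 25 protocols with group sizes
#' 12 variable flip angle, 8 inversion recovery, 1 saturation recovery,
#' 2 Look-Locker, and 2 MP2RAGE. The members vary exactly the implementation
#' details that drive method-dependence of the observed T1: repetition time,
#' flip-angle sets, TI/TS grids, pulse durations, and the semi-solid
#' saturation efficiency of the inversion pulse.
#'
#' @return A list of `t1_protocol` objects with unique, stable ids.
#' @export
default_protocol_suite <- function() {
  deg <- pi / 180
  ti_grid <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  suite <- list(
    vfa_protocol("vfa01", c(3, 6, 9, 13, 18) * deg, 0.015, 1.0e-4),
    vfa_protocol("vfa02", c(4, 18) * deg, 0.015, 6e-5),
    vfa_protocol("vfa03", c(2, 5, 10, 15, 20) * deg, 0.010, 6e-5),
    vfa_protocol("vfa04", c(3, 17) * deg, 0.010, 6e-5),
    vfa_protocol("vfa05", c(4, 10, 16, 22) * deg, 0.020, 8e-5),
    vfa_protocol("vfa06", c(5, 26) * deg, 0.020, 7e-5),
    vfa_protocol("vfa07", c(3, 7, 12, 17, 22) * deg, 0.025, 9e-5),
    vfa_protocol("vfa08", c(2, 10, 18) * deg, 0.012, 8e-5),
    vfa_protocol("vfa09", c(6, 21) * deg, 0.018, 7e-5),
    vfa_protocol("vfa10", c(4, 9, 14, 19, 24, 29) * deg, 0.030, 8e-5),
    vfa_protocol("vfa11", c(3, 14) * deg, 0.008, 5e-5),
    vfa_protocol("vfa12", c(2, 4, 8, 12, 16, 20) * deg, 0.015, 6e-5),
    ir_protocol("ir01", ti_grid(0.05, 3.0, 8), 10, inv_dur = 0.010),
    ir_protocol("ir02", c(0.1, 0.3, 0.6, 1.0, 1.5, 2.5, 4.0), 12,
                inv_dur = 0.010, inv_model = "composite"),
    ir_protocol("ir03", ti_grid(0.05, 2.0, 5), 8, inv_dur = 0.005),
    ir_protocol("ir04", ti_grid(0.03, 5.0, 10), 15, inv_dur = 0.015,
                inv_model = "composite"),
    ir_protocol("ir05", ti_grid(0.10, 4.0, 6), 10, inv_dur = 0.020),
    ir_protocol("ir06", ti_grid(0.05, 1.8, 8), 6, inv_dur = 0.008,
                inv_model = "composite"),
    ir_protocol("ir07", ti_grid(0.20, 6.0, 7), 14, inv_dur = 0.015),
    ir_protocol("ir08", ti_grid(0.04, 3.5, 9), 9, inv_dur = 0.010,
                inv_sat_scale = 0.8, inv_model = "composite"),
    sr_protocol("sr01", c(0.1, 0.25, 0.5, 1, 2, 3, 4.5, 6), 8,
                sat_dur = 0, exc_dur = 1e-4),
    ll_protocol("ll01", 5 * deg, 0.150, 32, 10, delay1 = 0.10,
                inv_dur = 0.010, exc_dur = 1e-4),
    ll_protocol("ll02", 12 * deg, 0.060, 60, 8, delay1 = 0.05,
                inv_dur = 0.010, exc_dur = 5e-5, inv_sat_scale = 0.9),
    mp2rage_protocol("mp01", 0.7, 2.5, c(4, 5) * deg, 0.008, 32, 6,
                     inv_dur = 0.010, exc_dur = 1e-4),
    mp2rage_protocol("mp02", 1.0, 3.2, c(7, 5) * deg, 0.007, 40, 8,
                     inv_dur = 0.010, exc_dur = 1e-4)
  )
  names(suite) <- vapply(suite, `[[`, character(1), "id")
  suite
}

#' Summarize a protocol suite as a tibble
#'
#' @param suite A list of `t1_protocol` objects.
#' @return A tibble with one row per protocol (`id`, `type`, `n_measurements`).
#' @export
protocol_summary <- function(suite) {
  purrr::map_dfr(suite, function(pr) {
    n <- switch(pr$type,
      inversion_recovery = length(pr$TI),
      saturation_recovery = length(pr$TS),
      variable_flip_angle = length(pr$flips),
      look_locker = pr$n_readouts,
      mp2rage = 2L)
    tibble(id = pr$id, type = pr$type, n_measurements = n)
  })
}

# --- protocol file I/O (YAML; seconds and degrees on disk) -----------------

protocol_to_entry <- function(pr) {
  deg <- 180 / pi
  e <- list(id = pr$id, type = pr$type)
  e <- c(e, switch(pr$type,
    inversion_recovery = list(TI = as.numeric(pr$TI), TR = pr$TR,
      inv_dur = pr$inv_dur, exc_dur = pr$exc_dur,
      exc_flip = pr$exc_flip * deg, inv_sat_scale = pr$inv_sat_scale,
      inv_model = pr$inv_model),
    saturation_recovery = list(TS = as.numeric(pr$TS), TR = pr$TR,
      sat_dur = pr$sat_dur, exc_dur = pr$exc_dur,
      exc_flip = pr$exc_flip * deg),
    variable_flip_angle = list(flips = as.numeric(pr$flips) * deg,
      TR = pr$TR, exc_dur = pr$exc_dur),
    look_locker = list(readout_flip = pr$readout_flip * deg,
      spacing = pr$spacing, n_readouts = pr$n_readouts, TR = pr$TR,
      delay1 = pr$delay1, inv_dur = pr$inv_dur, exc_dur = pr$exc_dur,
      inv_sat_scale = pr$inv_sat_scale, inv_model = pr$inv_model,
      ll_correction = pr$ll_correction),
    mp2rage = list(TI1 = pr$TI1, TI2 = pr$TI2,
      flips = as.numeric(pr$flips) * deg, spacing = pr$spacing,
      n_per_block = pr$n_per_block, TR = pr$TR, inv_dur = pr$inv_dur,
      exc_dur = pr$exc_dur, inv_sat_scale = pr$inv_sat_scale,
      inv_model = pr$inv_model)
  ))
  e
}

required_fields <- list(
  inversion_recovery = c("TI", "TR"),
  saturation_recovery = c("TS", "TR"),
  variable_flip_angle = c("flips", "TR"),
  look_locker = c("readout_flip", "spacing", "n_readouts", "TR"),
  mp2rage = c("TI1", "TI2", "flips", "spacing", "n_per_block", "TR")
)

entry_to_protocol <- function(e) {
  rad <- pi / 180
  id <- e$id %||% "?"
  if (is.null(e$id)) stop_protocol(id, "id", "missing")
  if (is.null(e$type) || !e$type %in% names(required_fields)) {
    stop_protocol(id, "type", "missing or unknown sequence type")
  }
  for (f in required_fields[[e$type]]) {
    if (is.null(e[[f]])) stop_protocol(id, f, "missing required field")
  }
  g <- function(f, default) if (is.null(e[[f]])) default else e[[f]]
  switch(e$type,
    inversion_recovery = ir_protocol(id, unlist(e$TI), e$TR,
      inv_dur = g("inv_dur", 0.010), exc_dur = g("exc_dur", 0.001),
      exc_flip = g("exc_flip", 90) * rad,
      inv_sat_scale = g("inv_sat_scale", 1),
      inv_model = g("inv_model", "rect")),
    saturation_recovery = sr_protocol(id, unlist(e$TS), e$TR,
      sat_dur = g("sat_dur", 0.001), exc_dur = g("exc_dur", 0.001),
      exc_flip = g("exc_flip", 90) * rad),
    variable_flip_angle = vfa_protocol(id, unlist(e$flips) * rad, e$TR,
      exc_dur = g("exc_dur", 0.001)),
    look_locker = ll_protocol(id, e$readout_flip * rad, e$spacing,
      e$n_readouts, e$TR, delay1 = g("delay1", 0.1),
      inv_dur = g("inv_dur", 0.010), exc_dur = g("exc_dur", 0.001),
      inv_sat_scale = g("inv_sat_scale", 1),
      inv_model = g("inv_model", "composite"),
      ll_correction = g("ll_correction", "flip_angle")),
    mp2rage = mp2rage_protocol(id, e$TI1, e$TI2, unlist(e$flips) * rad,
      e$spacing, e$n_per_block, e$TR, inv_dur = g("inv_dur", 0.010),
      exc_dur = g("exc_dur", 0.001), inv_sat_scale = g("inv_sat_scale", 1),
      inv_model = g("inv_model", "composite"))
  )
}

#' Write a protocol suite to a YAML file
#'
#' On disk, times are in seconds and flip angles in degrees.
#'
#' @param suite A list of `t1_protocol` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocols <- function(suite, path) {
  entries <- lapply(unname(suite), protocol_to_entry)
  yaml::write_yaml(list(protocols = entries), path, precision = 15)
  invisible(path)
}

#' Read a protocol suite from a YAML file
#'
#' Validates the schema (required timing fields per sequence type) and
#' converts degrees to radians.
#'
#' @param path Path to a YAML suite written by [write_protocols()] or by hand.
#' @return A named list of `t1_protocol` objects.
#' @export
load_protocols <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$protocols)) {
    stop("protocol file must have a top-level 'protocols' list", call. = FALSE)
  }
  suite <- lapply(doc$protocols, entry_to_protocol)
  ids <- vapply(suite, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate protocol ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(suite) <- ids
  suite
}

`%||%` <- function(a, b) if (is.null(a)) b else a
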