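mt_param_names <- c("m0s", "T1f", "T2f", "Tx", "T1s", "T2s")

#' Five-point central finite difference
#'
#' Differentiates a scalar function of an [mt_params()] set with the 5-point
#' central stencil `(-f(+2h) + 8 f(+h) - 8 f(-h) + f(-2h)) / (12 h)`, which is
#' exact on quartic polynomials and 4th-order accurate on smooth functions.
#' The step is relative, `h = rel_step * p0[[which]]`; for `m0s`, which may
#' legitimately be zero (the Bloch limit), an absolute step floor `h_min`
#' keeps the stencil well-posed. The floor applies to `m0s` only: the other
#' five parameters are strictly positive and span orders of magnitude
#' (`T2s` is ~1e-5 s), so a global absolute floor would swamp them.
#'
#' @param f A function taking an `mt_params` object and returning a finite
#'   scalar.
#' @param p0 The expansion point, an [mt_params()] object.
#' @param which One of `"m0s", "T1f", "T2f", "Tx", "T1s", "T2s"`.
#' @param rel_step Relative step size (default 1e-3).
#' @param h_min Absolute step floor applied to `m0s` only (default 1e-4 at
#'   the default `rel_step`).
#' @return The derivative `df/dp` at `p0`.
#' @export
central_difference <- function(f, p0, which, rel_step = 1e-3,
                               h_min = 1e-4) {
  stopifnot(which %in% mt_param_names)
  x0 <- p0[[which]]
  h <- rel_step * x0
  if (which == "m0s") h <- max(h, h_min)
  if (h <= 0) stop("step size must be positive for parameter ", which,
                   call. = FALSE)
  eval_at <- function(k) {
    p <- p0
    p[[which]] <- x0 + k * h
    v <- f(p)
    if (!is.finite(v)) {
      stop("objective not finite at stencil node ", which, " = ",
           format(x0 + k * h), call. = FALSE)
    }
    v
  }
  (-eval_at(2) + 8 * eval_at(1) - 8 * eval_at(-1) + eval_at(-2)) / (12 * h)
}

#' Derivative table of the observed T1 over a cohort and protocol suite
#'
#' For every (ROI, protocol) pair, simulates the protocol, fits the observed
#' T1 with the protocol's native procedure, and differentiates it with
#' respect to each of the six MT parameters by [central_difference()]. This
#' is the analysis dataset of the whole package: 6 records per pair.
#'
#' Pairs whose fit fails to converge at any stencil node are excluded with a
#' warning (never imputed); the number of exclusions is reported.
#'
#' @param suite A list of `t1_protocol` objects (e.g.
#'   [default_protocol_suite()]).
#' @param cohort A cohort tibble with columns `roi_id` and the six MT
#'   parameters (see [generate_cohort()]).
#' @param rel_step,h_min Finite-difference settings (see
#'   [central_difference()]).
#' @param lineshape Semi-solid lineshape for the simulations.
#' @return A tibble with columns `roi_id`, `seq_id`, `seq_type`, `param`,
#'   `deriv` (s per parameter unit), and `norm_deriv`
#'   (`|deriv| * mean(param over cohort)`, in seconds).
#' @export
compute_derivative_table <- function(suite, cohort, rel_step = 1e-3,
                                     h_min = 1e-4,
                                     lineshape = "super_lorentzian") {
  mu <- vapply(mt_param_names, function(nm) mean(cohort[[nm]]), numeric(1))
  n_excluded <- 0L
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    p0 <- as_mt_params(cohort[i, ])
    roi <- cohort$roi_id[i]
    purrr::map_dfr(suite, function(pr) {
      f <- function(p) {
        fit <- observed_t1(pr, p, lineshape = lineshape)
        if (!isTRUE(fit$converged)) return(NA_real_)
        fit$T1o
      }
      d <- vapply(mt_param_names, function(nm) {
        tryCatch(central_difference(f, p0, nm, rel_step, h_min),
                 error = function(e) NA_real_)
      }, numeric(1))
      if (anyNA(d)) {
        n_excluded <<- n_excluded + sum(is.na(d))
        keep <- !is.na(d)
      } else {
        keep <- rep(TRUE, 6)
      }
      tibble(roi_id = roi, seq_id = pr$id, seq_type = pr$type,
             param = mt_param_names[keep], deriv = unname(d[keep]))
    })
  })
  if (n_excluded > 0) {
    warning(n_excluded, " derivative record(s) excluded: fit did not ",
            "converge at a stencil node", call. = FALSE)
  }
  rows$norm_deriv <- abs(rows$deriv) * mu[rows$param]
  class(rows) <- c("t1_deriv_table", class(rows))
  attr(rows, "param_means") <- mu
  rows
}

#' Sensitivity summary per MT parameter
#'
#' For each parameter: the mean normalized sensitivity
#' `mean(|dT1o/dp|) * mean(p)` (in seconds, comparable across parameters) and
#' the coefficient of variation `sd(|dT1o/dp|) / mean(|dT1o/dp|)`, both taken
#' over the full (ROI x sequence) grid.
#'
#' @param records A derivative table from [compute_derivative_table()].
#' @param param_means Optional named vector of cohort-mean parameter values;
#'   defaults to the means stored on `records`.
#' @return A tibble with columns `param`, `sensitivity` (s), `cv`, and
#'   `n_records`.
#' @export
summarize_sensitivity <- function(records, param_means = NULL) {
  mu <- param_means %||% attr(records, "param_means")
  if (is.null(mu)) stop("param_means required (cohort means per parameter)",
                        call. = FALSE)
  if (nrow(records) == 0) stop("no derivative records", call. = FALSE)
  out <- records |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(
      mean_abs = mean(abs(.data$deriv)),
      cv = stats::sd(abs(.data$deriv)) / mean(abs(.data$deriv)),
      n_records = dplyr::n(),
      .groups = "drop"
    )
  out$sensitivity <- unname(out$mean_abs * mu[out$param])
  out <- out[order(match(out$param, mt_param_names)), ]
  tibble::as_tibble(out[, c("param", "sensitivity", "cv", "n_records")])
}
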