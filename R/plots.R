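#' Plot a derivative table (sensitivity overview)
#'
#' One point per (ROI, sequence, parameter): the absolute derivative of the
#' observed T1, normalized by the cohort-mean parameter value so the six
#' parameters share a scale, colored by sequence type.
#'
#' @param object A `t1_deriv_table` from [compute_derivative_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t1_deriv_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$param <- factor(d$param, levels = mt_param_names)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$param, y = .data$norm_deriv,
                                  colour = .data$seq_type)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.7,
                         position = ggplot2::position_jitter(width = 0.25,
                                                             seed = 1)) +
    ggplot2::labs(x = "MT parameter", colour = "sequence type",
                  y = expression("|" * partialdiff * T[1 * o] / partialdiff *
                                   p * "|" %.% mu[p] ~ "(s)")) +
    ggplot2::theme_minimal()
}

#' Plot a variance decomposition as stacked R-squared components
#'
#' @param object A `t1_var_decomp` or a `t1_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t1_var_decomp <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$kind == "r2" & d$component != "r2_full", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$response, y = .data$value,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "derivative response", y = expression(R^2),
                  fill = "component") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.t1_var_decomp
#' @export
autoplot.t1_run <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$summary[, c("param", "r2_fixed", "r2_roi", "r2_seqtype",
                       "r2_indseq")],
    -"param", names_to = "component", values_to = "value")
  d$param <- factor(d$param, levels = mt_param_names)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$param, y = .data$value,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "derivative response", y = expression(R^2),
                  fill = "component") +
    ggplot2::theme_minimal()
}

#' Plot a simulated signal set
#'
#' @param s A signal tibble from [simulate_signals()].
#' @return A ggplot object.
#' @export
plot_signals <- function(s) {
  ggplot2::ggplot(s, ggplot2::aes(x = .data$abscissa, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "abscissa", y = "signal",
                  title = s$protocol_id[1]) +
    ggplot2::theme_minimal()
}
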