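#' Assemble the modeling data for one derivative response
#'
#' Filters the derivative table to one response (one MT parameter's
#' derivative), attaches the six ROI-level MT covariates, and standardizes
#' them (z-scored across the distinct ROI values). Standardization matters:
#' the six parameters span five orders of magnitude (T2s ~ 1e-5 s vs
#' T1f ~ 2 s) and unstandardized mixed-model fits are ill-conditioned.
#'
#' @param records A derivative table ([compute_derivative_table()]) or any
#'   tibble with columns `roi_id`, `seq_id`, `seq_type`, `deriv`, and either
#'   a `param` column (long format) or the six covariate columns.
#' @param response Which derivative to model (one of the six MT parameter
#'   names); ignored when `records` has no `param` column.
#' @param cohort Cohort tibble supplying the covariates when `records` does
#'   not carry them.
#' @return A tibble with `roi_id`, `seq_id`, `seq_type`, `deriv`, and the six
#'   standardized covariates; unstandardized covariate means/sds are kept as
#'   attributes `centers` and `scales`.
#' @export
prepare_model_data <- function(records, response = NULL, cohort = NULL) {
  d <- tibble::as_tibble(records)
  if ("param" %in% names(d)) {
    if (is.null(response)) stop("response required", call. = FALSE)
    d <- dplyr::filter(d, .data$param == response)
    d <- d[, c("roi_id", "seq_id", "seq_type", "deriv")]
  }
  if (!all(mt_param_names %in% names(d))) {
    if (is.null(cohort)) {
      stop("cohort required to supply the MT covariates", call. = FALSE)
    }
    d <- dplyr::left_join(d, cohort[, c("roi_id", mt_param_names)],
                          by = "roi_id")
  }
  roi_vals <- dplyr::distinct(d[, c("roi_id", mt_param_names)])
  centers <- vapply(mt_param_names, function(nm) mean(roi_vals[[nm]]),
                    numeric(1))
  scales <- vapply(mt_param_names, function(nm) stats::sd(roi_vals[[nm]]),
                   numeric(1))
  scales[scales == 0 | !is.finite(scales)] <- 1
  for (nm in mt_param_names) {
    d[[nm]] <- (d[[nm]] - centers[[nm]]) / scales[[nm]]
  }
  attr(d, "centers") <- centers
  attr(d, "scales") <- scales
  d
}

mixed_formula <- function(fixed) {
  rhs <- if (length(fixed) == 0) "1" else paste(fixed, collapse = " + ")
  stats::as.formula(paste("deriv ~", rhs,
                          "+ (1 | roi_id) + (1 | seq_type) + (1 | seq_id)"))
}

lmer_quiet <- function(formula, data) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = FALSE,
                                control = ctrl)),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Fit the linear mixed-effects model of one derivative's variability
#'
#' Models the derivative of the observed T1 with respect to one MT parameter
#' as a linear function of the six (standardized) MT parameters plus an
#' intercept (fixed effects), with Gaussian random intercepts for the ROI,
#' the sequence type, and the individual sequence (nested ids), estimated by
#' maximum likelihood. No random slopes. Variance components that collapse
#' to the boundary are reported as zero (singular fits are not errors).
#'
#' @inheritParams prepare_model_data
#' @param fixed Character vector of fixed-effect covariates (subset of the
#'   six MT parameter names; empty = intercept-only).
#' @return An object of class `t1_mixed_fit` wrapping the `lmerMod` fit.
#' @export
fit_mixed_model <- function(records, response = NULL, cohort = NULL,
                            fixed = mt_param_names) {
  d <- prepare_model_data(records, response, cohort)
  model <- lmer_quiet(mixed_formula(fixed), d)
  structure(list(model = model, data = d, fixed = fixed,
                 response = response %||% "deriv"),
            class = "t1_mixed_fit")
}

#' @export
print.t1_mixed_fit <- function(x, ...) {
  cat("<t1_mixed_fit> response:", x$response, "\n")
  print(x$model)
  invisible(x)
}

#' @rdname t1sens-tidiers
#' @export
tidy.t1_mixed_fit <- function(x, ...) {
  fe <- lme4::fixef(x$model)
  tibble::tibble(term = names(fe), estimate = unname(fe))
}

#' @rdname t1sens-tidiers
#' @export
glance.t1_mixed_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(response = x$response),
                   nakagawa_r2(x),
                   tibble::tibble(AIC = stats::AIC(x$model),
                                  logLik = as.numeric(stats::logLik(x$model))))
}

variance_components <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  v <- stats::setNames(vc$vcov, vc$grp)
  c(roi = unname(v["roi_id"] %|0|% 0),
    seq_type = unname(v["seq_type"] %|0|% 0),
    seq_id = unname(v["seq_id"] %|0|% 0),
    resid = unname(v["Residual"] %|0|% 0))
}

`%|0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Nakagawa--Schielzeth R-squared decomposition of a mixed fit
#'
#' All components share one denominator
#' `D = var(fixed predictions) + sum(random-intercept variances) + residual
#' variance`, so the printed additivity identity
#' `R2_full = R2_fixed + R2_roi + R2_seqtype + R2_indseq` holds exactly:
#' `R2_fixed = var(fixed)/D`, each random share is its variance over `D`,
#' and `R2_full = 1 - residual/D`.
#'
#' @param fit A `t1_mixed_fit` (or `lmerMod`).
#' @return A one-row tibble: `r2_fixed`, `r2_roi`, `r2_seqtype`,
#'   `r2_indseq`, `r2_full`.
#' @export
nakagawa_r2 <- function(fit) {
  model <- if (inherits(fit, "t1_mixed_fit")) fit$model else fit
  var_f <- stats::var(stats::predict(model, re.form = NA))
  v <- variance_components(model)
  D <- var_f + v[["roi"]] + v[["seq_type"]] + v[["seq_id"]] + v[["resid"]]
  if (D <= 0) stop("total variance is zero; R2 undefined", call. = FALSE)
  tibble::tibble(
    r2_fixed = var_f / D,
    r2_roi = v[["roi"]] / D,
    r2_seqtype = v[["seq_type"]] / D,
    r2_indseq = v[["seq_id"]] / D,
    r2_full = 1 - v[["resid"]] / D
  )
}

# all 2^6 subsets of the fixed effects as a logical matrix (rows = subsets,
# columns = parameters), row order = bitmask value
subset_mask <- function() {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6))[, 6:1])
  colnames(m) <- mt_param_names
  m
}

#' Fixed-effect subset scan (Nakagawa R2 and AIC for all 64 subsets)
#'
#' Refits the mixed model (random structure unchanged, maximum likelihood)
#' for every subset of the six fixed effects and records the Nakagawa
#' `R2_fixed`, AIC, and log-likelihood of each. Feeds both the Shapley
#' attribution and the AIC overfitting check.
#'
#' @inheritParams fit_mixed_model
#' @return A tibble with one row per subset: `subset` (comma-separated
#'   names, `"(none)"` for the intercept-only model), `k` (subset size),
#'   `r2_fixed`, `AIC`, `logLik`, plus six logical indicator columns.
#' @export
fixed_subset_scan <- function(records, response = NULL, cohort = NULL) {
  d <- prepare_model_data(records, response, cohort)
  m <- subset_mask()
  rows <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    vars <- mt_param_names[m[i, ]]
    fit <- tryCatch(lmer_quiet(mixed_formula(vars), d),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(subset = paste(vars, collapse = ","),
                            k = length(vars), r2_fixed = NA_real_,
                            AIC = NA_real_, logLik = NA_real_))
    }
    tibble::tibble(
      subset = if (length(vars) == 0) "(none)" else paste(vars, collapse = ","),
      k = length(vars),
      r2_fixed = nakagawa_r2(fit)$r2_fixed,
      AIC = stats::AIC(fit),
      logLik = as.numeric(stats::logLik(fit))
    )
  })
  dplyr::bind_cols(rows, tibble::as_tibble(m))
}

#' Shapley attribution of the fixed-effect R-squared
#'
#' Distributes the joint Nakagawa `R2_fixed` of the full six-parameter model
#' over the individual MT parameters: the share of parameter `i` is the
#' average, over all subsets `S` not containing `i` with Shapley weights
#' `|S|! (6 - |S| - 1)! / 6!`, of the gain `R2_fixed(S + i) - R2_fixed(S)`.
#' Each subset model keeps the full random structure and is refit by maximum
#' likelihood. By the efficiency axiom the shares sum to the full model's
#' `R2_fixed` (the intercept-only model has `R2_fixed = 0` exactly).
#'
#' @inheritParams fit_mixed_model
#' @param scan Optional precomputed [fixed_subset_scan()] for these data.
#' @return A tibble with columns `param` and `share`.
#' @export
shapley_fixed_r2 <- function(records, response = NULL, cohort = NULL,
                             scan = NULL) {
  scan <- scan %||% fixed_subset_scan(records, response, cohort)
  m <- subset_mask()
  # r2 indexed by bitmask value of the subset
  mask_val <- as.integer(m %*% 2^(0:5))
  r2 <- numeric(64)
  r2[mask_val + 1] <- scan$r2_fixed
  if (anyNA(r2)) {
    warning("some subset fits failed; their R2 treated as 0", call. = FALSE)
    r2[is.na(r2)] <- 0
  }
  shares <- vapply(seq_along(mt_param_names), function(i) {
    bit <- 2^(i - 1)
    without <- which(bitwAnd(mask_val, bit) == 0)
    sum(vapply(without, function(j) {
      k <- sum(m[j, ])
      w <- factorial(k) * factorial(6 - k - 1) / factorial(6)
      w * (r2[mask_val[j] + bit + 1] - r2[mask_val[j] + 1])
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(param = mt_param_names, share = shares)
}

#' AIC scan over all fixed-effect subsets
#'
#' Ranks all 64 subset models by AIC (maximum-likelihood fits) and reports
#' whether the full six-parameter model lies within `delta_ok` AIC of the
#' best subset — the overfitting check that motivates keeping the full model
#' for every response.
#'
#' @inheritParams shapley_fixed_r2
#' @param delta_ok AIC window regarded as equivalent support (default 2).
#' @return A tibble sorted by AIC with `delta_aic` and a `full_model`
#'   indicator; the attribute `full_within` flags whether the full model is
#'   within `delta_ok` of the best.
#' @export
aic_subset_scan <- function(records, response = NULL, cohort = NULL,
                            scan = NULL, delta_ok = 2) {
  scan <- scan %||% fixed_subset_scan(records, response, cohort)
  out <- dplyr::arrange(scan, .data$AIC)
  out$delta_aic <- out$AIC - out$AIC[1]
  out$full_model <- out$k == 6
  attr(out, "full_within") <- out$delta_aic[out$full_model] <= delta_ok
  out
}

#' Variance decomposition of one derivative response
#'
#' Fits the full mixed model, computes the Nakagawa R-squared partition into
#' fixed, ROI, sequence-type, and individual-sequence components, and
#' (optionally) the per-parameter Shapley shares of the fixed-effect
#' R-squared and the AIC subset scan.
#'
#' @inheritParams fit_mixed_model
#' @param shapley Compute the Shapley attribution (64 refits)?
#' @param aic Keep the AIC subset ranking?
#' @return An object of class `t1_var_decomp`: a list with `response`,
#'   `r2` (one-row tibble), `shapley`, `aic`, `fit`, and `coefficients`
#'   (fixed effects on the standardized and the natural scale).
#' @export
decompose_variance <- function(records, response = NULL, cohort = NULL,
                               shapley = TRUE, aic = shapley) {
  fit <- fit_mixed_model(records, response, cohort)
  r2 <- nakagawa_r2(fit)
  scan <- if (shapley || aic) {
    fixed_subset_scan(records, response, cohort)
  }
  shap <- if (shapley) shapley_fixed_r2(scan = scan)
  aic_tab <- if (aic) aic_subset_scan(scan = scan)
  fe <- lme4::fixef(fit$model)
  scales <- attr(fit$data, "scales")
  coefs <- tibble::tibble(
    term = names(fe),
    estimate_std = unname(fe),
    estimate = unname(ifelse(names(fe) == "(Intercept)", fe,
                             fe / scales[names(fe)]))
  )
  structure(list(response = fit$response, r2 = r2, shapley = shap,
                 aic = aic_tab, fit = fit, coefficients = coefs),
            class = "t1_var_decomp")
}

#' @export
print.t1_var_decomp <- function(x, ...) {
  cat("<t1_var_decomp> response:", x$response, "\n")
  print(x$r2)
  if (!is.null(x$shapley)) {
    cat("Shapley shares of r2_fixed:\n")
    print(x$shapley)
  }
  invisible(x)
}

#' Tidiers for t1sens result objects
#'
#' [generics::tidy()] and [generics::glance()] methods: `tidy()` returns the
#' component-level breakdown (R2 components and Shapley shares for a
#' decomposition; coefficient estimates for fits), `glance()` a one-row
#' summary.
#'
#' @param x A `t1_fit`, `t1_mixed_fit`, or `t1_var_decomp` object.
#' @param ... Unused.
#' @name t1sens-tidiers
NULL

#' @rdname t1sens-tidiers
#' @export
tidy.t1_var_decomp <- function(x, ...) {
  r2 <- tidyr::pivot_longer(x$r2, dplyr::everything(),
                            names_to = "component", values_to = "value")
  r2$kind <- "r2"
  out <- r2
  if (!is.null(x$shapley)) {
    sh <- tibble::tibble(component = paste0("r2_", x$shapley$param),
                         value = x$shapley$share, kind = "shapley")
    out <- dplyr::bind_rows(out, sh)
  }
  dplyr::bind_cols(tibble::tibble(response = x$response), out)
}

#' @rdname t1sens-tidiers
#' @export
glance.t1_var_decomp <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(response = x$response), x$r2)
}
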