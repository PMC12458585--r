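default_roi_ids <- c("WM", "anterior_CC", "posterior_CC", "cortical_GM",
                     "caudate", "putamen", "pallidum", "thalamus",
                     "hippocampus")

#' Default physical ranges of the cohort generator
#'
#' Per-parameter bounds (in SI units) within which the synthetic ROI cohort
#' is drawn. The ranges reflect typical 3 T magnetization-transfer literature
#' magnitudes for human brain; they are stand-ins for measured per-ROI
#' values, which are not shipped with the package.
#'
#' @return A named list of length-2 numeric vectors `c(lo, hi)`.
#' @export
default_cohort_ranges <- function() {
  list(m0s = c(0.05, 0.30), T1f = c(1.2, 2.2), T2f = c(0.04, 0.10),
       Tx = c(0.02, 0.10), T1s = c(0.2, 0.5), T2s = c(5e-6, 1.5e-5))
}

# published 3 T white-matter anchors: free-pool T1 and semi-solid T1
wm_anchors <- c(T1f = 1.84, T1s = 0.34)

#' Generate a synthetic ROI cohort of MT parameter sets
#'
#' Draws one six-parameter MT set per brain region of interest (9 ROIs by
#' default: whole white matter, anterior/posterior corpus callosum, cortical
#' gray matter, caudate, putamen, pallidum, thalamus, hippocampus) with a
#' seeded Latin hypercube, scaled into per-parameter physical ranges. The WM
#' row is anchored to the published 3 T values T1f = 1.84 s and
#' T1s = 0.34 s whenever those values lie inside the configured range (a
#' degenerate point range elsewhere takes precedence, which keeps fully
#' degenerate cohorts exactly uniform).
#'
#' The draw is deterministic given `seed` and does not disturb the caller's
#' RNG state.
#'
#' @param seed Integer seed.
#' @param ranges Named list of `c(lo, hi)` bounds per parameter; see
#'   [default_cohort_ranges()].
#' @param roi_ids Character vector of ROI identifiers.
#' @return A tibble with columns `roi_id, m0s, T1f, T2f, Tx, T1s, T2s`.
#' @export
generate_cohort <- function(seed = 1, ranges = default_cohort_ranges(),
                            roi_ids = default_roi_ids) {
  for (nm in mt_param_names) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2]) {
      stop("invalid range for ", nm, call. = FALSE)
    }
  }
  n <- length(roi_ids)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  lh <- lhs::randomLHS(n, length(mt_param_names))
  colnames(lh) <- mt_param_names
  out <- tibble::tibble(roi_id = roi_ids)
  for (nm in mt_param_names) {
    r <- ranges[[nm]]
    out[[nm]] <- r[1] + (r[2] - r[1]) * lh[, nm]
  }
  for (nm in names(wm_anchors)) {
    r <- ranges[[nm]]
    if (wm_anchors[[nm]] >= r[1] && wm_anchors[[nm]] <= r[2] &&
        "WM" %in% out$roi_id) {
      out[[nm]][out$roi_id == "WM"] <- wm_anchors[[nm]]
    }
  }
  out
}

#' Generate a synthetic mixed-model dataset with known structure
#'
#' Produces records shaped like the derivative table, with a response built
#' from the exact statistical structure the variance decomposition assumes:
#' linear fixed effects in the six (standardized) MT covariates, Gaussian
#' random intercepts for ROI, sequence type, and individual sequence, and
#' Gaussian residual noise. Used to test parameter and variance-share
#' recovery.
#'
#' @param beta Named numeric vector of fixed-effect coefficients; names from
#'   `c("(Intercept)", "m0s", "T1f", "T2f", "Tx", "T1s", "T2s")`; missing
#'   names are taken as zero.
#' @param sigma Named numeric vector of standard deviations with names
#'   `roi`, `seq_type`, `seq_id`, `resid` (missing names are zero).
#' @param n_roi,n_seq Grid size (default: 9 ROIs x 25 sequences).
#' @param n_type Number of sequence types the sequences are assigned to
#'   (round-robin, nested ids).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A tibble with columns `roi_id`, `seq_id`, `seq_type`, the six
#'   covariates (constant within ROI), and `deriv` (the response).
#' @export
generate_mixed_dataset <- function(beta = c("(Intercept)" = 0),
                                   sigma = c(resid = 1),
                                   n_roi = 9, n_seq = 25, n_type = 5,
                                   seed = 1) {
  if (any(sigma < 0)) stop("variance components must be non-negative",
                           call. = FALSE)
  b <- stats::setNames(numeric(7),
                       c("(Intercept)", mt_param_names))
  b[names(beta)] <- beta
  s <- stats::setNames(numeric(4), c("roi", "seq_type", "seq_id", "resid"))
  s[names(sigma)] <- sigma
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  X <- matrix(stats::rnorm(n_roi * 6), n_roi, 6,
              dimnames = list(NULL, mt_param_names))
  type_of_seq <- rep_len(seq_len(n_type), n_seq)
  u_roi <- stats::rnorm(n_roi, sd = s[["roi"]])
  u_type <- stats::rnorm(n_type, sd = s[["seq_type"]])
  u_seq <- stats::rnorm(n_seq, sd = s[["seq_id"]])
  grid <- tidyr::expand_grid(roi = seq_len(n_roi), seq = seq_len(n_seq))
  eps <- stats::rnorm(nrow(grid), sd = s[["resid"]])
  fixed <- b[["(Intercept)"]] +
    as.vector(X[grid$roi, , drop = FALSE] %*% b[mt_param_names])
  out <- tibble::tibble(
    roi_id = paste0("roi", grid$roi),
    seq_id = paste0("seq", grid$seq),
    seq_type = paste0("type", type_of_seq[grid$seq])
  )
  for (nm in mt_param_names) out[[nm]] <- X[grid$roi, nm]
  parts <- list(fixed = fixed, roi = u_roi[grid$roi],
                seq_type = u_type[type_of_seq[grid$seq]],
                seq_id = u_seq[grid$seq], resid = eps)
  out$deriv <- parts$fixed + parts$roi + parts$seq_type + parts$seq_id +
    parts$resid
  # realized variance contributions of this draw (for recovery tests):
  # each in-sample covariance between two parts is split evenly between
  # them, so the contributions sum exactly to var(deriv)
  P <- do.call(cbind, parts)
  S <- stats::cov(P)
  attr(out, "realized_var") <- stats::setNames(rowSums(S), names(parts))
  out
}

#' Write / read a cohort as CSV
#'
#' Plain CSV with `roi_id` plus the six parameter columns, SI units, full
#' double precision.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `path` (write) or the cohort tibble (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(c("roi_id", mt_param_names), names(out))
  if (length(missing) > 0) {
    stop("cohort file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out
}
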