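test_that("mixed-model fits recover known structure without random noise", {
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 1, m0s = 2,
                                       T2f = -1),
                              sigma = c(resid = 1e-8), seed = 21)
  fit <- fit_mixed_model(d)
  fe <- lme4::fixef(fit$model)
  # coefficients are on the standardized scale; divide by the realized
  # covariate sd to return to the generating scale
  sc <- attr(fit$data, "scales")
  expect_equal(unname(fe["m0s"]) / sc[["m0s"]], 2, tolerance = 1e-4)
  expect_equal(unname(fe["T2f"]) / sc[["T2f"]], -1, tolerance = 1e-4)
  v <- t1sens:::variance_components(fit$model)
  expect_lt(max(v[c("roi", "seq_type", "seq_id")]), 1e-6)
  r2 <- nakagawa_r2(fit)
  expect_equal(r2$r2_fixed, 1, tolerance = 1e-4)
  expect_equal(r2$r2_full, 1, tolerance = 1e-4)
})

test_that("row order does not affect the likelihood fit", {
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 0.5, T1f = 1),
                              sigma = c(seq_type = 0.4, seq_id = 0.2,
                                        resid = 0.3), seed = 22)
  f1 <- fit_mixed_model(d)
  set.seed(1)
  f2 <- fit_mixed_model(d[sample(nrow(d)), ])
  # identical up to optimizer path noise (the likelihood is exchangeable)
  expect_equal(lme4::fixef(f1$model), lme4::fixef(f2$model),
               tolerance = 1e-5)
  expect_equal(nakagawa_r2(f1), nakagawa_r2(f2), tolerance = 1e-4)
})

test_that("the R2 components add up exactly (shared denominator)", {
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 0, m0s = 1, Tx = 0.5),
                              sigma = c(roi = 0.2, seq_type = 0.5,
                                        seq_id = 0.3, resid = 0.4),
                              seed = 23)
  r2 <- nakagawa_r2(fit_mixed_model(d))
  expect_equal(r2$r2_full,
               r2$r2_fixed + r2$r2_roi + r2$r2_seqtype + r2$r2_indseq,
               tolerance = 1e-8)
})

test_that("a pure-noise response has near-zero explained variance", {
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 0),
                              sigma = c(resid = 1), seed = 24)
  r2 <- nakagawa_r2(fit_mixed_model(d))
  expect_lt(r2$r2_full, 0.15)
})

test_that("Shapley shares concentrate on the active covariate and satisfy
           efficiency", {
  # a wide ROI grid keeps the covariates near-orthogonal, so the share
  # concentrates on the active one (9 ROIs leave sizeable spurious
  # correlations that Shapley faithfully spreads)
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 0, T1s = 2),
                              sigma = c(seq_id = 0.1, resid = 0.1),
                              n_roi = 60, seed = 25)
  scan <- fixed_subset_scan(d)
  expect_equal(nrow(scan), 64)
  expect_true("(none)" %in% scan$subset)
  sh <- shapley_fixed_r2(scan = scan)
  full_r2 <- scan$r2_fixed[scan$k == 6]
  expect_equal(sum(sh$share), full_r2, tolerance = 1e-8)
  expect_gt(sh$share[sh$param == "T1s"], 0.8 * full_r2)
  expect_lt(max(sh$share[sh$param != "T1s"]), 0.1 * full_r2)
})

test_that("perfectly correlated covariates split their share equally", {
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 0, m0s = 1),
                              sigma = c(resid = 0.2), seed = 26)
  d$T2f <- d$m0s   # duplicate informative covariate
  sh <- shapley_fixed_r2(d)
  expect_equal(sh$share[sh$param == "m0s"], sh$share[sh$param == "T2f"],
               tolerance = 1e-6)
})

test_that("AIC subset scan prefers the generating covariates", {
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 0, m0s = 1.5,
                                       T1f = 1, T2s = -1),
                              sigma = c(seq_id = 0.05, resid = 0.1),
                              seed = 27)
  aic <- aic_subset_scan(d)
  best <- aic[1, ]
  expect_true(all(c(best$m0s, best$T1f, best$T2s)))
  expect_true(is.logical(attr(aic, "full_within")))
  # the full model stays close to the best subset (no large penalty)
  expect_lt(aic$delta_aic[aic$k == 6], 10)
})

test_that("adding pure-noise covariates costs AIC on average", {
  delta <- vapply(1:20, function(s) {
    d <- generate_mixed_dataset(beta = c("(Intercept)" = 0, m0s = 1),
                                sigma = c(resid = 0.5), seed = 100 + s)
    dat <- prepare_model_data(d)
    a_true <- stats::AIC(t1sens:::lmer_quiet(
      t1sens:::mixed_formula("m0s"), dat))
    a_full <- stats::AIC(t1sens:::lmer_quiet(
      t1sens:::mixed_formula(c("m0s", "T1f", "T2f", "Tx", "T1s", "T2s")),
      dat))
    a_full - a_true
  }, numeric(1))
  expect_gt(mean(delta), 0)
})

test_that("decompose_variance bundles the pieces coherently", {
  d <- generate_mixed_dataset(beta = c("(Intercept)" = 1, Tx = 1),
                              sigma = c(seq_type = 0.3, resid = 0.2),
                              seed = 28)
  dec <- decompose_variance(d, shapley = TRUE)
  expect_s3_class(dec, "t1_var_decomp")
  expect_equal(sum(dec$shapley$share), dec$r2$r2_fixed, tolerance = 1e-8)
  td <- tidy(dec)
  expect_true(all(c("response", "component", "value") %in% names(td)))
  gl <- glance(dec)
  expect_equal(gl$r2_full, dec$r2$r2_full)
  expect_named(tidy(dec$fit), c("term", "estimate"))
})
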