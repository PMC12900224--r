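test_that("counterfactual specs validate strata and reject TTD covariates", {
  expect_error(counterfactual_spec(reference = c(0, 20), target = c(15, 30)),
               "disjoint")
  expect_error(
    counterfactual_spec(covariates = list(covariate("ttd_min", "rcs"))),
    "exclude the TTD term")
  expect_error(counterfactual_spec(reps = 0), "reps")
})

test_that("the reference model reproduces the reference acceptance rate", {
  reg <- generate_registry(small_config(n = 4000, seed = 71))
  d <- reg$donors
  # intercept-only: fitted probability is identically the observed rate
  spec0 <- counterfactual_spec(covariates = list(), reps = 10)
  fit0 <- fit_reference(d, spec0)
  r <- mean(d$utilized[d$ttd_min < 10])
  expect_equal(unname(plogis(fit0$coefficients[1])), r, tolerance = 1e-8)
  # with covariates, the ML identity still holds for the mean
  spec <- counterfactual_spec(covariates = cf_covariates(), reps = 10)
  fit <- fit_reference(d, spec)
  ref <- d[d$ttd_min < 10, ]
  pr <- project_acceptance(fit, ref)
  expect_equal(pr$predicted_rate, r, tolerance = 1e-8)
})

test_that("projection standardizes over the target covariate distribution", {
  spec0 <- counterfactual_spec(covariates = list(), reps = 10)
  set.seed(72)
  ref <- data.frame(ttd_min = runif(3000, 0, 10),
                    utilized = runif(3000) < 0.4)
  tgt <- data.frame(ttd_min = runif(500, 15, 30),
                    utilized = runif(500) < 0.2)
  fit <- fit_reference(ref, spec0)
  pr <- project_acceptance(fit, tgt)
  expect_equal(pr$predicted_rate, mean(ref$utilized), tolerance = 1e-8)
  expect_error(project_acceptance(fit, tgt[0, ]), "empty")

  # known covariate shift: predicted rate matches the analytic
  # logistic-normal standardization integral
  set.seed(73)
  nref <- 30000
  xr <- rnorm(nref)
  refd <- data.frame(ttd_min = runif(nref, 0, 10), x = xr,
                     utilized = runif(nref) < plogis(-0.5 + 0.8 * xr))
  xt <- rnorm(8000, mean = 1)
  tgtd <- data.frame(ttd_min = runif(8000, 15, 30), x = xt,
                     utilized = FALSE)
  spec <- counterfactual_spec(covariates = list(covariate("x", "linear")),
                              reps = 10)
  fit <- fit_reference(refd, spec)
  pr <- project_acceptance(fit, tgtd)
  oracle <- integrate(function(s) plogis(-0.5 + 0.8 * s) * dnorm(s, 1, 1),
                      -Inf, Inf)$value
  expect_lt(abs(pr$predicted_rate - oracle), 0.02)
})

test_that("summary arithmetic on acceptance rates is exact", {
  s1 <- summarize_counterfactual(29.4, 34.4, 13080)
  expect_equal(s1$absolute_pp, 5.0, tolerance = 1e-9)
  s2 <- summarize_counterfactual(12.1, 30.6, 2957)
  expect_equal(s2$absolute_pp, 18.5, tolerance = 1e-9)
  s3 <- summarize_counterfactual(25, 25, 100)
  expect_equal(s3$absolute_pp, 0)
  expect_equal(s3$relative_pct, 0)
  expect_equal(s3$extra_organs, 0)
  expect_true(is.na(summarize_counterfactual(0, 10, 100)$relative_pct))
  # invariant structure: extra = n * absolute / 100, relative = abs/actual
  s <- summarize_counterfactual(20, 27, 500)
  expect_equal(s$extra_organs, 500 * s$absolute_pp / 100)
  expect_equal(s$relative_pct, 100 * s$absolute_pp / 20)
})

test_that("percentile interval endpoints are order statistics", {
  v <- c(9, 1, 7, 3, 10, 2, 8, 5, 4, 6)
  ci <- dcdlivers:::percentile_ci(v, 0.95)
  expect_equal(unname(ci), c(1, 10))
  ci80 <- dcdlivers:::percentile_ci(v, 0.80)
  expect_equal(unname(ci80), c(1, 9))
  expect_equal(unname(dcdlivers:::percentile_ci(rep(4.2, 50), 0.95)),
               c(4.2, 4.2))
})

test_that("bootstrap intervals behave sensibly end to end", {
  reg <- generate_registry(small_config(n = 5000, seed = 74))
  spec <- counterfactual_spec(covariates = cf_covariates(), reps = 200,
                              seed = 5)
  res <- counterfactual_analysis(reg$donors, spec)
  expect_s3_class(res, "counterfactual_result")
  # interval ordering around every point estimate
  expect_lte(res$predicted_ci[1], res$predicted_rate_pct)
  expect_gte(res$predicted_ci[2], res$predicted_rate_pct)
  expect_lte(res$absolute_ci[1], res$absolute_pp)
  expect_gte(res$absolute_ci[2], res$absolute_pp)
  expect_lte(res$extra_ci[1], res$extra_organs)
  expect_gte(res$extra_ci[2], res$extra_organs)
  expect_equal(res$extra_organs,
               res$n_target * res$absolute_pp / 100, tolerance = 1e-10)
  # determinism under the spec seed
  res2 <- counterfactual_analysis(reg$donors, spec)
  expect_identical(res$extra_ci, res2$extra_ci)
})

test_that("estimated extra organs are monotone in the injected decline", {
  extras <- vapply(c(0.02, 0.065, 0.12), function(sl) {
    reg <- generate_registry(small_config(n = 4000, seed = 75,
                                          util_decline_slope = sl))
    spec <- counterfactual_spec(covariates = cf_covariates(), reps = 30,
                                seed = 6)
    counterfactual_analysis(reg$donors, spec)$extra_organs
  }, numeric(1))
  expect_true(all(diff(extras) >= 0))
})
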