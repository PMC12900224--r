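test_that("covariate encoding follows the declared treatments", {
  d <- data.frame(w = c(10, 20, 40), flag = c(0, 1, 1),
                  grp = c("a", "b", "c"), x = c(1, 50, 100))
  spec <- model_spec("y", "logistic", response = "y",
                     covariates = list(covariate("w", "log2"),
                                       covariate("flag", "linear"),
                                       covariate("grp", "categorical",
                                                 ref = "a")))
  enc <- encode_covariates(d, spec)
  expect_equal(unname(enc$X[1, "log2_w"]), log2(10), tolerance = 1e-12)
  # doubling a log2 covariate moves its encoded value by exactly 1
  expect_equal(unname(enc$X[2, "log2_w"] - enc$X[1, "log2_w"]), 1)
  expect_equal(colnames(enc$X), c("log2_w", "flag", "grp=b", "grp=c"))
  expect_equal(unname(enc$X[, "grp=b"]), c(0, 1, 0))

  # interaction of a binary flag with a 3-column spline block
  spec2 <- model_spec("y", "logistic", response = "y",
                      covariates = list(
                        covariate("x", "rcs", knots = c(1, 30, 60, 100)),
                        covariate("flag", "linear")),
                      interactions = list(c("flag", "x")))
  enc2 <- encode_covariates(d, spec2)
  expect_length(enc2$groups[["flag:x"]], 3L)

  dz <- data.frame(w = c(0, 1), y = c(0, 1))
  spec3 <- model_spec("y", "logistic", response = "y",
                      covariates = list(covariate("w", "log2")))
  expect_error(encode_covariates(dz, spec3), "offset")
})

test_that("Cox fit recovers a known hazard ratio and respects rank invariance", {
  d <- two_group_exponential(5000, hr = 2, seed = 61)
  spec <- model_spec("t", "cox", time = "time", event = "event",
                     covariates = list(covariate("z", "linear")))
  fit <- fit_cox(d, spec)
  hr <- exp(unname(fit$coefficients["z"]))
  expect_gte(hr, 1.85)
  expect_lte(hr, 2.16)
  # adding a constant to all times changes nothing (rank property)
  d2 <- d; d2$time <- d2$time + 1000
  fit2 <- fit_cox(d2, spec)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-5)
})

test_that("Cox fit rejects degenerate inputs by name", {
  d <- two_group_exponential(100, hr = 1, seed = 62)
  spec <- model_spec("t", "cox", time = "time", event = "event",
                     covariates = list(covariate("z", "linear")))
  d0 <- d; d0$event <- 0L
  expect_error(fit_cox(d0, spec), "no events")
  dc <- d; dc$z <- 1
  expect_error(fit_cox(dc, spec), "z")
})

test_that("logistic fit satisfies its maximum-likelihood identities", {
  set.seed(63)
  d <- data.frame(y = rbinom(4000, 1, 0.5))
  spec0 <- model_spec("y", "logistic", response = "y")
  fit0 <- fit_logistic(d, spec0)
  expect_lt(abs(unname(fit0$coefficients[1])), 3 * sqrt(4 / 4000))

  n <- 10000
  x <- rnorm(n)
  d2 <- data.frame(x = x, y = rbinom(n, 1, plogis(0.7 * x)))
  spec <- model_spec("y", "logistic", response = "y",
                     covariates = list(covariate("x", "linear")))
  fit <- fit_logistic(d2, spec)
  b <- fit$coefficients["x"]
  se <- sqrt(fit$vcov["x", "x"])
  expect_lt(abs(b - 0.7), 3 * se)
  # mean fitted probability equals the observed rate (score equation)
  enc <- encode_covariates(d2, spec)
  p <- plogis(drop(cbind(1, enc$X) %*% fit$coefficients))
  expect_equal(mean(p), mean(d2$y), tolerance = 1e-8)

  d2$y <- 1L
  expect_error(fit_logistic(d2, spec), "single class")
})

test_that("Kaplan-Meier estimates match the product-limit by hand", {
  km <- km_curve(1:4, rep(1, 4))
  expect_equal(km$curve$surv[km$curve$time == 2], 0.5)
  km0 <- km_curve(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(km0$curve$surv == 1))
  # mixed example against direct product-limit enumeration
  t <- c(1, 2, 2, 3, 5, 6); e <- c(1, 1, 0, 1, 0, 1)
  km2 <- km_curve(t, e)
  oracle <- function(tt) {
    s <- 1
    for (u in sort(unique(t[e == 1]))) {
      if (u <= tt) s <- s * (1 - sum(t == u & e == 1) / sum(t >= u))
    }
    s
  }
  for (tt in sort(unique(t))) {
    expect_equal(km2$curve$surv[km2$curve$time == tt][1], oracle(tt),
                 tolerance = 1e-12)
  }
  # number-at-risk table
  expect_equal(unname(km2$at_risk[1, "2"]), 5)
})

test_that("MI analysis with zero missingness equals the single fit", {
  reg <- generate_registry(small_config(n = 1200, seed = 64))
  coh <- apply_inclusion(reg$donors, reg$transplants)
  spec <- model_spec("graft", "cox", time = "graft_time_days",
                     event = "graft_event",
                     covariates = list(covariate("ttd_min", "rcs"),
                                       covariate("donor_age", "linear")),
                     horizon_days = 365)
  sets <- impute_pmm(coh$outcome, vars = "peak_alt", m = 3, seed = 1)
  mi <- run_mi_analysis(sets, spec)
  single <- fit_cox(coh$outcome, spec)
  expect_equal(mi$pooled$coefficients, single$coefficients, tolerance = 1e-12)
  expect_equal(unname(diag(mi$pooled$vcov)), unname(diag(single$vcov)),
               tolerance = 1e-12)
  expect_s3_class(mi$curves$ttd_min, "effect_curve")
})

test_that("a fit failure on any imputed dataset aborts with its index", {
  reg <- generate_registry(small_config(n = 400, seed = 65))
  coh <- apply_inclusion(reg$donors, reg$transplants)
  spec <- model_spec("graft", "cox", time = "graft_time_days",
                     event = "graft_event",
                     covariates = list(covariate("donor_age", "linear")))
  sets <- impute_pmm(coh$outcome, vars = "peak_alt", m = 3, seed = 1)
  sets[[2]]$graft_event <- 0L
  expect_error(run_mi_analysis(sets, spec), "imputed dataset 2")
})

test_that("fitted TTD effect curves approach the generating truth with n", {
  ise <- vapply(c(1500, 6000), function(n) {
    cfg <- small_config(n = n, seed = 66, util_intercept = 2,
                        graft_short_ttd_penalty = 0.8)
    reg <- generate_registry(cfg)
    coh <- apply_inclusion(reg$donors, reg$transplants)
    spec <- model_spec("graft", "cox", time = "graft_time_days",
                       event = "graft_event",
                       covariates = list(
                         covariate("ttd_min", "rcs", x_ref = 15),
                         covariate("donor_age", "linear"),
                         covariate("cold_ischemic_hours", "log2")))
    fit <- fit_cox(coh$outcome, spec)
    grid <- seq(quantile(reg$donors$ttd_min, 0.05),
                quantile(reg$donors$ttd_min, 0.95), length.out = 60)
    ec <- effect_curve(fit, fit$spline_specs$ttd_min, grid = grid)
    truth <- dcdlivers:::graft_ttd_loghr(grid, cfg) -
      dcdlivers:::graft_ttd_loghr(15, cfg)
    mean((log(ec$ratio) - truth)^2)
  }, numeric(1))
  expect_lt(ise[2], ise[1])
})
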