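test_that("intercept-only utilization at logit 0 accepts about half of donors", {
  cfg <- bare_config(n = 10000, seed = 11, slope = 0,
                     util_intercept = 0)
  reg <- generate_registry(cfg)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(reg$donors$utilized) - 0.5), 3 * se)
})

test_that("exponential baseline reproduces its closed-form median event time", {
  lambda <- 0.002
  cfg <- bare_config(
    n = 12000, seed = 12, util_intercept = 2, slope = 0,
    graft_base_rate = lambda, graft_short_ttd_penalty = 0,
    graft_covariate_effects = list(), censoring_rate = 0,
    follow_up_min_days = 1e7, follow_up_max_days = 1e7 + 1)
  reg <- generate_registry(cfg)
  expect_true(all(reg$transplants$graft_event == 1))
  med <- median(reg$transplants$graft_time_days)
  expect_lt(abs(med - log(2) / lambda) / (log(2) / lambda), 0.05)
})

test_that("generated event times match the configured survival function (KS)", {
  lambda <- 0.002
  cfg <- bare_config(
    n = 25000, seed = 13, util_intercept = 0, slope = 0,
    graft_base_rate = lambda, graft_short_ttd_penalty = 0,
    graft_covariate_effects = list(), censoring_rate = 0,
    follow_up_min_days = 1e7, follow_up_max_days = 1e7 + 1)
  reg <- generate_registry(cfg)
  t <- reg$transplants$graft_time_days
  expect_gte(length(t), 10000)
  ks <- suppressWarnings(ks.test(t[seq_len(10000)], pexp, rate = lambda))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seed and config reproduce identical tables", {
  cfg <- small_config(n = 500, seed = 42)
  a <- generate_registry(cfg)
  b <- generate_registry(cfg)
  expect_identical(a$donors, b$donors)
  expect_identical(a$transplants, b$transplants)
})

test_that("empirical acceptance converges to the analytic mean of the logit", {
  cfg <- small_config(n = 20000, seed = 14)
  reg <- generate_registry(cfg)
  p <- reg$truth$overall_acceptance
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(mean(reg$donors$utilized) - p), 4 * se)
})

test_that("TTD distribution is calibrated to median 13 with IQR width 8", {
  cfg <- small_config(n = 50000, seed = 15)
  ttd <- generate_registry(cfg)$donors$ttd_min
  expect_lt(abs(median(ttd) - 13), 0.3)
  expect_lt(abs(diff(quantile(ttd, c(0.25, 0.75))) - 8), 0.4)
})

test_that("truth summary is computed from the config, not the sample", {
  a <- truth_summary(small_config(n = 1000, seed = 1))
  b <- truth_summary(small_config(n = 1000, seed = 999))
  a$config$seed <- b$config$seed <- NULL
  expect_identical(a, b)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(generator_config(n_donors = 0), "n_donors")
  expect_error(generator_config(nrp_fraction = 1.5), "nrp_fraction")
  expect_error(generator_config(ttd_sdlog = -1), "ttd_sdlog")
  expect_error(generator_config(missingness = list(peak_alt = list(rate = 2))),
               "missingness\\$peak_alt")
})

test_that("missingness injection hits the requested rates", {
  reg <- generate_registry(small_config(n = 5000, seed = 16))
  d0 <- inject_missingness(reg$donors, list(), seed = 1)
  expect_identical(d0, reg$donors)

  d <- inject_missingness(
    reg$donors,
    list(peak_alt = list(rate = 0.2, depends = "donor_age"),
         peak_albumin = list(rate = 1.0)),
    seed = 2)
  frac <- mean(is.na(d$peak_alt))
  expect_gte(frac, 0.18)
  expect_lte(frac, 0.22)
  expect_true(all(is.na(d$peak_albumin)))
  # MAR: missingness probability actually depends on the age covariate
  expect_gt(abs(mean(d$donor_age[is.na(d$peak_alt)]) -
                  mean(d$donor_age[!is.na(d$peak_alt)])), 0.5)
})

test_that("the primary exposures cannot be blanked", {
  reg <- generate_registry(small_config(n = 100, seed = 17))
  expect_error(inject_missingness(reg$donors, list(ttd_min = list(rate = 0.1))),
               "ttd_min")
  expect_error(inject_missingness(reg$donors,
                                  list(asystolic_min = list(rate = 0.1))),
               "excluded")
})

test_that("analytic counterfactual truth matches hand-computed closed forms", {
  # no TTD effect on utilization -> no extra organs
  cfg0 <- bare_config(n = 10000, slope = 0)
  expect_equal(true_counterfactual(cfg0, c(15, 30))$extra_organs, 0)

  # slope 0 with covariates present -> still 0
  cfg0c <- small_config(n = 10000, util_decline_slope = 0)
  expect_equal(true_counterfactual(cfg0c, c(15, 30))$extra_organs, 0,
               tolerance = 1e-10)

  # constant logit drop delta beyond the decline window, no covariates:
  # extra = n_stratum * (plogis(b0) - plogis(b0 - delta))
  b0 <- stats::qlogis(0.345)
  s <- 0.05
  cfg <- bare_config(n = 10000, slope = s)
  delta <- s * (45 - 15)
  tc <- true_counterfactual(cfg, c(45, 60))
  p_str <- plnorm(60, cfg$ttd_meanlog, cfg$ttd_sdlog) -
    plnorm(45, cfg$ttd_meanlog, cfg$ttd_sdlog)
  expect_equal(tc$n_stratum, 10000 * p_str, tolerance = 1e-12)
  expect_equal(tc$extra_organs,
               10000 * p_str * (plogis(b0) - plogis(b0 - delta)),
               tolerance = 1e-6)

  expect_error(true_counterfactual(cfg, c(1e6, 2e6)), "empty")
})

test_that("registry round-trips through delimited text", {
  reg <- generate_registry(small_config(n = 200, seed = 18))
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  back <- read_registry(dir)
  expect_equal(back$donors$ttd_min, reg$donors$ttd_min, tolerance = 1e-8)
  expect_identical(nrow(back$transplants), nrow(reg$transplants))
  expect_error(read_registry(file.path(dir, "nope")), "nope")
})
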