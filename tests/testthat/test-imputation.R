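test_that("Nelson-Aalen estimator matches hand computation", {
  expect_equal(nelson_aalen(c(1, 2, 3), c(1, 1, 1)),
               c(1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1))
  expect_equal(nelson_aalen(c(4, 9), c(0, 0)), c(0, 0))
  expect_equal(nelson_aalen(5, 1), 1)
  # ties and censoring against the survival package's estimator
  set.seed(21)
  t <- sample(1:20, 60, replace = TRUE)
  e <- rbinom(60, 1, 0.6)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1, ctype = 1)
  expect_equal(nelson_aalen(t, e),
               approx(sf$time, sf$cumhaz, xout = t, method = "constant",
                      yleft = 0, rule = 2)$y)
})

test_that("zero missingness yields m identical copies of the input", {
  reg <- generate_registry(small_config(n = 150, seed = 6))
  sets <- impute_pmm(reg$donors, vars = "peak_alt", m = 3, seed = 1)
  expect_length(sets, 3)
  expect_identical(sets[[1]], reg$donors)
  expect_identical(sets[[2]], reg$donors)
})

test_that("imputed values lie in the observed support of their variable", {
  reg <- generate_registry(small_config(n = 800, seed = 7))
  d <- inject_missingness(reg$donors,
                          list(peak_alt = list(rate = 0.25,
                                               depends = "donor_age"),
                               hypertension = list(rate = 0.15)),
                          seed = 3)
  sets <- impute_pmm(d, vars = c("peak_alt", "hypertension"), m = 4,
                     seed = 4)
  obs <- d$peak_alt[!is.na(d$peak_alt)]
  for (s in sets) {
    expect_false(anyNA(s$peak_alt))
    expect_true(all(s$peak_alt %in% obs))
    expect_true(all(s$hypertension %in% c(TRUE, FALSE)))
  }
  # imputations differ between datasets (bootstrap + random draws)
  miss <- which(is.na(d$peak_alt))
  expect_false(identical(sets[[1]]$peak_alt[miss], sets[[2]]$peak_alt[miss]))
})

test_that("primary exposures and hopeless targets are refused", {
  reg <- generate_registry(small_config(n = 50, seed = 8))
  expect_error(impute_pmm(reg$donors, vars = "ttd_min"), "never imputed")
  d <- reg$donors
  d$cause_of_death[1:10] <- NA
  expect_error(impute_pmm(d, vars = "cause_of_death"), "two levels")
})

test_that("MAR imputation recovers a downstream coefficient", {
  set.seed(31)
  n <- 2000
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, sd = 0.6)
  y <- rbinom(n, 1, plogis(0.5 * x2))
  d <- data.frame(x1 = x1, x2 = x2, y = y)
  # MAR: x2 missing with probability depending on observed x1
  miss <- runif(n) < plogis(-1.5 + x1)
  d$x2[miss] <- NA
  sets <- impute_pmm(d, vars = "x2", predictors = "x1", auxiliaries = "y",
                     m = 20, seed = 5)
  spec <- model_spec("y", "logistic", response = "y",
                     covariates = list(covariate("x2", "linear")))
  pooled <- pool_fits(lapply(sets, fit_logistic, spec = spec))
  est <- pooled$terms[pooled$terms$term == "x2", ]
  expect_lt(abs(est$estimate - 0.5), 2 * est$se)
})

test_that("Rubin pooling identities hold", {
  mk <- function(b, v) list(coefficients = c(b = b),
                            vcov = matrix(v, dimnames = list("b", "b")),
                            groups = list(b = 1L))
  # identical fits: B = 0, pooled variance = W
  p <- pool_fits(list(mk(1.3, 0.4), mk(1.3, 0.4), mk(1.3, 0.4)))
  expect_equal(unname(p$B[1, 1]), 0)
  expect_equal(unname(p$vcov[1, 1]), 0.4)
  # m = 2, estimates {0, 2}, within-variances {1, 1}:
  # pooled 1, variance 1 + 1.5 * 2 = 4
  p2 <- pool_fits(list(mk(0, 1), mk(2, 1)))
  expect_equal(unname(p2$coefficients), 1)
  expect_equal(unname(p2$vcov[1, 1]), 4)
  # m = 20 random fits: matrix pooling matches the scalar Rubin formula
  set.seed(41)
  bs <- rnorm(20); vs <- runif(20, 0.5, 1.5)
  p3 <- pool_fits(mapply(mk, bs, vs, SIMPLIFY = FALSE))
  expect_equal(unname(p3$vcov[1, 1]),
               mean(vs) + (1 + 1 / 20) * var(bs), tolerance = 1e-12)
  # pooled variance never falls below the within component
  expect_true(all(diag(p3$vcov) >= diag(p3$W)))
  # dimension mismatch names the offending fit
  bad <- list(mk(0, 1), list(coefficients = c(a = 1), vcov = matrix(1),
                             groups = NULL))
  expect_error(pool_fits(bad), "fit 2")
})

test_that("pooled intervals under MCAR have near-nominal coverage", {
  set.seed(51)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    n <- 400
    x1 <- rnorm(n)
    x2 <- 0.7 * x1 + rnorm(n, sd = 0.7)
    y <- rbinom(n, 1, plogis(0.6 * x2))
    d <- data.frame(x1 = x1, x2 = x2, y = y)
    d$x2[runif(n) < 0.2] <- NA
    sets <- impute_pmm(d, vars = "x2", predictors = "x1", auxiliaries = "y",
                       m = 5, seed = r)
    spec <- model_spec("y", "logistic", response = "y",
                       covariates = list(covariate("x2", "linear")))
    pooled <- pool_fits(lapply(sets, fit_logistic, spec = spec))
    est <- pooled$terms[pooled$terms$term == "x2", ]
    hits <- hits + (est$conf.low <= 0.6 && 0.6 <= est$conf.high)
  }
  coverage <- hits / n_rep
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})
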