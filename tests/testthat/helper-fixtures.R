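# Small generator configurations used across the suite. The covariate
# effects mirror the package defaults unless a test needs them off.

small_config <- function(n = 2000, seed = 1, ...) {
  generator_config(n_donors = n, seed = seed, ...)
}

# Covariate-free configuration: utilization depends on TTD only (or on
# nothing, when slope = 0), so closed forms are exact logistic means.
bare_config <- function(n = 2000, seed = 1, slope = 0.065, ...) {
  generator_config(n_donors = n, seed = seed,
                   util_covariate_effects = list(),
                   util_decline_slope = slope, ...)
}

# Counterfactual covariate list matching the generating utilization
# model (linear in age and BMI, log2 in peak ALT).
cf_covariates <- function() {
  list(covariate("donor_age", "linear"),
       covariate("donor_bmi", "linear"),
       covariate("peak_alt", "log2"))
}

# Two-group exponential survival data with a known hazard ratio.
two_group_exponential <- function(n, hr, base_rate = 0.01, seed = 1) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  t <- rexp(n, base_rate * hr^z)
  cens <- runif(n, 0, 2 * log(2) / base_rate)
  data.frame(z = z, time = pmin(t, cens), event = as.integer(t <= cens))
}
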