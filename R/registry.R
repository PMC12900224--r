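#' Configuration for the synthetic donor registry
#'
#' Defines the generating truth of a synthetic donation-after-circulatory-
#' death (DCD) donor registry: how warm-ischemia times, donor and
#' recipient covariates, liver utilization decisions, and post-transplant
#' survival are drawn. Every downstream stage of the pipeline can be
#' tested against this known truth.
#'
#' The defaults describe a registry of the size and shape reported for
#' the US national DCD liver experience: time to death (TTD, withdrawal
#' of life support to asystole) log-normal with median 13 min and
#' interquartile width 8 min; roughly 10% of donors recovered with
#' normothermic regional perfusion (NRP), distinguished from super-rapid
#' recovery (SRR) by long asystole-to-flush times; a utilization logit
#' that is flat for short TTD and declines linearly between
#' \code{decline_start} and \code{decline_end} minutes; and a graft
#' hazard carrying a short-TTD penalty (ischemic injury accrued before
#' death) but no prolonged-TTD penalty.
#'
#' Utilization covariate effects are linear on scales (possibly log2)
#' on which the generated covariates are Gaussian, so the population
#' acceptance rate and the counterfactual truth have closed forms
#' ([true_counterfactual()]).
#'
#' @param n_donors number of potential donors.
#' @param seed integer seed; identical seed and config give byte-identical
#'   output.
#' @param ttd_meanlog,ttd_sdlog log-normal parameters of TTD in minutes.
#' @param nrp_fraction proportion of donors on the NRP pathway.
#' @param asystolic per-pathway log-normal parameters (minutes) for the
#'   asystole-to-flush interval.
#' @param util_intercept utilization logit at reference covariates and
#'   short TTD.
#' @param util_decline_start,util_decline_end TTD window (minutes) over
#'   which the utilization logit declines linearly; flat outside.
#' @param util_decline_slope logit decline per minute inside the window.
#' @param util_covariate_effects named list of linear utilization-logit
#'   effects; each element is \code{list(beta, center)} and the names
#'   must be \code{donor_age}, \code{donor_bmi} or \code{log2_peak_alt}.
#'   Set to \code{list()} for a covariate-free utilization model.
#' @param graft_base_rate baseline daily hazard of the graft-loss
#'   composite (graft failure or death).
#' @param graft_short_ttd_penalty log-hazard added at TTD 0, fading
#'   linearly to 0 at \code{graft_short_ttd_ref} minutes.
#' @param graft_short_ttd_ref TTD (minutes) at which the short-TTD
#'   penalty vanishes.
#' @param graft_covariate_effects named list of log-hazard effects
#'   (\code{donor_age}, \code{log2_cold_ischemic}), each
#'   \code{list(beta, center)}.
#' @param censoring_rate probability of early random loss to follow-up.
#' @param follow_up_min_days,follow_up_max_days administrative censoring
#'   window (staggered study entry; every subject has at least
#'   \code{follow_up_min_days} of potential follow-up).
#' @param missingness named list of missingness requests applied by
#'   [inject_missingness()]; each element \code{list(rate, depends)}.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_donors = 41443L,
                             seed = 1L,
                             ttd_meanlog = log(13),
                             ttd_sdlog = 0.4493,
                             nrp_fraction = 0.096,
                             asystolic = list(
                               SRR = list(meanlog = log(12), sdlog = 0.35),
                               NRP = list(meanlog = log(60), sdlog = 0.30)),
                             util_intercept = stats::qlogis(0.345),
                             util_decline_start = 15,
                             util_decline_end = 45,
                             util_decline_slope = 0.065,
                             util_covariate_effects = list(
                               donor_age = list(beta = -0.02, center = 40),
                               donor_bmi = list(beta = -0.045, center = 27),
                               log2_peak_alt = list(beta = -0.20, center = log2(82))),
                             graft_base_rate = -log(0.9) / 365,
                             graft_short_ttd_penalty = 0.35,
                             graft_short_ttd_ref = 10,
                             graft_covariate_effects = list(
                               donor_age = list(beta = 0.012, center = 40),
                               log2_cold_ischemic = list(beta = 0.15, center = log2(6))),
                             censoring_rate = 0.1,
                             follow_up_min_days = 365,
                             follow_up_max_days = 1825,
                             missingness = list(
                               peak_alt = list(rate = 0.10, depends = "donation_year"),
                               peak_bilirubin = list(rate = 0.15, depends = "donor_age"),
                               peak_albumin = list(rate = 0.15, depends = "donation_year"))) {
  cfg <- as.list(environment())
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid generator configuration: field '", field, "' ", why)
  }
  chk(is.numeric(cfg$n_donors) && cfg$n_donors >= 1, "n_donors", "must be >= 1")
  chk(cfg$ttd_sdlog > 0, "ttd_sdlog", "must be positive")
  chk(cfg$nrp_fraction >= 0 && cfg$nrp_fraction <= 1, "nrp_fraction",
      "must be in [0, 1]")
  for (pw in names(cfg$asystolic)) {
    chk(cfg$asystolic[[pw]]$sdlog > 0, paste0("asystolic$", pw, "$sdlog"),
        "must be positive")
  }
  chk(cfg$util_decline_end > cfg$util_decline_start, "util_decline_end",
      "must exceed util_decline_start")
  chk(cfg$util_decline_slope >= 0, "util_decline_slope", "must be nonnegative")
  chk(cfg$graft_base_rate > 0, "graft_base_rate", "must be positive")
  chk(cfg$censoring_rate >= 0 && cfg$censoring_rate <= 1, "censoring_rate",
      "must be in [0, 1]")
  for (v in names(cfg$missingness)) {
    r <- cfg$missingness[[v]]$rate
    chk(is.numeric(r) && r >= 0 && r <= 1, paste0("missingness$", v, "$rate"),
        "must be in [0, 1]")
  }
  cfg$n_donors <- as.integer(cfg$n_donors)
  structure(cfg, class = "generator_config")
}

# Marginal (Gaussian) law of the utilization covariate score
# S = sum_j beta_j (z_j - center_j) on the generator's covariate scales.
covariate_score_law <- function(config) {
  scales <- list(
    donor_age = c(mean = 40, sd = 12),
    donor_bmi = c(mean = 27, sd = 5),
    log2_peak_alt = c(mean = log(82) / log(2), sd = 1.0 / log(2)))
  mu <- 0; v <- 0
  for (nm in names(config$util_covariate_effects)) {
    eff <- config$util_covariate_effects[[nm]]
    sc <- scales[[nm]]
    if (is.null(sc)) stop("unknown utilization covariate effect '", nm, "'")
    mu <- mu + eff$beta * (sc[["mean"]] - eff$center)
    v <- v + (eff$beta * sc[["sd"]])^2
  }
  c(mean = mu, sd = sqrt(v))
}

# Utilization logit contribution of TTD: 0 before decline_start, then a
# linear drop, flat again beyond decline_end.
util_ttd_logit <- function(ttd, config) {
  -config$util_decline_slope *
    pmin(pmax(ttd - config$util_decline_start, 0),
         config$util_decline_end - config$util_decline_start)
}

# Short-TTD log-hazard penalty on the graft-loss composite.
graft_ttd_loghr <- function(ttd, config) {
  config$graft_short_ttd_penalty *
    pmax(config$graft_short_ttd_ref - ttd, 0) / config$graft_short_ttd_ref
}

# Gauss-Hermite nodes/weights by Golub-Welsch; deterministic.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
}

# E[plogis(a + S)] for S ~ N(mu, sd); vectorized over a; exact when sd = 0.
expected_logistic <- function(a, mu, sd, n_nodes = 60L) {
  if (sd == 0) return(stats::plogis(a + mu))
  gh <- gauss_hermite(n_nodes)
  s <- mu + sqrt(2) * sd * gh$nodes
  w <- gh$weights / sqrt(pi)
  drop(stats::plogis(outer(a, s, "+")) %*% w)
}

#' Generate a synthetic donor registry
#'
#' Draws a donor table, a transplant table for the utilized donors, and
#' a [TruthSummary][true_counterfactual] describing the generating truth
#' (analytic, seed-invariant). Donor covariates are drawn independently
#' of TTD; utilization is Bernoulli with logit
#' \code{util_intercept + f(TTD) + covariate score}; graft-loss and
#' death times are exponential with the configured short-TTD log-hazard
#' penalty; censoring is independent (random early loss plus uniform
#' administrative censoring).
#'
#' @param config a [generator_config()].
#' @return list with \code{donors}, \code{transplants}, \code{truth}.
#' @export
generate_registry <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_donors
  set.seed(config$seed)

  ttd <- stats::rlnorm(n, config$ttd_meanlog, config$ttd_sdlog)
  pathway_true <- ifelse(stats::runif(n) < config$nrp_fraction, "NRP", "SRR")
  asy <- numeric(n)
  for (pw in c("SRR", "NRP")) {
    sel <- pathway_true == pw
    asy[sel] <- stats::rlnorm(sum(sel), config$asystolic[[pw]]$meanlog,
                              config$asystolic[[pw]]$sdlog)
  }
  # SBP < 50 mm Hg occurs part-way through the agonal phase
  sbp_frac <- stats::rbeta(n, 4, 2)
  fttd <- sbp_frac * ttd + asy

  donors <- data.frame(
    donor_id = sprintf("D%06d", seq_len(n)),
    ttd_min = ttd,
    asystolic_min = asy,
    fttd_min = fttd,
    donor_age = stats::rnorm(n, 40, 12),
    donor_bmi = stats::rnorm(n, 27, 5),
    donor_sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.35, 0.65)),
    cause_of_death = sample(
      c("cerebrovascular", "anoxia_pdca", "drug_overdose", "head_trauma", "other"),
      n, replace = TRUE, prob = c(0.19, 0.29, 0.15, 0.27, 0.10)),
    hypertension = stats::runif(n) < 0.30,
    diabetes = stats::runif(n) < 0.12,
    blood_group = sample(c("A", "AB", "B", "O"), n, replace = TRUE,
                         prob = c(0.37, 0.04, 0.12, 0.47)),
    peak_alt = stats::rlnorm(n, log(82), 1.0),
    peak_bilirubin = stats::rlnorm(n, log(0.9), 0.7),
    peak_albumin = stats::rnorm(n, 3.6, 0.6),
    peak_sodium = stats::rnorm(n, 148, 8),
    donation_year = sample(2010:2024, n, replace = TRUE),
    uncontrolled = FALSE,
    stringsAsFactors = FALSE)

  logit <- config$util_intercept + util_ttd_logit(ttd, config)
  covx <- list(donor_age = donors$donor_age,
               donor_bmi = donors$donor_bmi,
               log2_peak_alt = log2(donors$peak_alt))
  for (nm in names(config$util_covariate_effects)) {
    eff <- config$util_covariate_effects[[nm]]
    logit <- logit + eff$beta * (covx[[nm]] - eff$center)
  }
  donors$utilized <- stats::runif(n) < stats::plogis(logit)
  donors$pathway <- classify_pathway(donors$asystolic_min)

  transplants <- generate_transplants(donors[donors$utilized, , drop = FALSE],
                                      config)
  truth <- truth_summary(config)
  list(donors = donors, transplants = transplants, truth = truth)
}

generate_transplants <- function(udonors, config) {
  m <- nrow(udonors)
  tx <- data.frame(
    donor_id = udonors$donor_id,
    recipient_age = stats::rnorm(m, 57, 10),
    recipient_bmi = stats::rnorm(m, 28, 5),
    recipient_sex = sample(c("F", "M"), m, replace = TRUE, prob = c(0.33, 0.67)),
    meld = pmax(6, stats::rnorm(m, 22, 8)),
    diagnosis = sample(c("alcohol", "hcc", "nash", "cholestatic", "alf",
                         "hcv", "other"),
                       m, replace = TRUE,
                       prob = c(0.30, 0.17, 0.20, 0.05, 0.02, 0.08, 0.18)),
    dialysis = stats::runif(m) < 0.06,
    rec_diabetes = stats::runif(m) < 0.25,
    status1a = stats::runif(m) < 0.01,
    medical_condition = sample(c("home", "hospital", "icu"), m, replace = TRUE,
                               prob = c(0.85, 0.11, 0.04)),
    functional_status = sample(c("<=60", "70", "80", "90", "100"), m,
                               replace = TRUE,
                               prob = c(0.35, 0.30, 0.25, 0.08, 0.02)),
    ethnicity = sample(c("white", "asian", "black", "hispanic", "other"), m,
                       replace = TRUE, prob = c(0.67, 0.03, 0.10, 0.17, 0.03)),
    waitlist_days = stats::rlnorm(m, log(60), 1.2),
    cold_ischemic_hours = stats::rlnorm(m, log(6), 0.35),
    machine_perfusion = sample(c("none", "normothermic", "hypothermic"), m,
                               replace = TRUE, prob = c(0.76, 0.22, 0.02)),
    multiorgan = FALSE,
    stringsAsFactors = FALSE)

  loghr <- graft_ttd_loghr(udonors$ttd_min, config)
  covx <- list(donor_age = udonors$donor_age,
               log2_cold_ischemic = log2(tx$cold_ischemic_hours))
  for (nm in names(config$graft_covariate_effects)) {
    eff <- config$graft_covariate_effects[[nm]]
    loghr <- loghr + eff$beta * (covx[[nm]] - eff$center)
  }
  rate <- config$graft_base_rate * exp(loghr)
  # graft-loss composite = min(pure graft failure, death)
  t_fail <- stats::rexp(m, rate * 0.55)
  t_death <- stats::rexp(m, rate * 0.45)
  t_graft <- pmin(t_fail, t_death)
  cens_admin <- stats::runif(m, config$follow_up_min_days, config$follow_up_max_days)
  cens_early <- ifelse(stats::runif(m) < config$censoring_rate,
                       stats::runif(m, 0, config$follow_up_min_days), Inf)
  cens <- pmin(cens_admin, cens_early)
  tx$graft_time_days <- pmin(t_graft, cens)
  tx$graft_event <- as.integer(t_graft <= cens)
  tx$patient_time_days <- pmin(t_death, cens)
  tx$patient_event <- as.integer(t_death <= cens)

  los_true <- stats::rlnorm(m, log(10), 0.5)
  died_pre <- t_graft < los_true
  tx$los_days <- ifelse(died_pre, t_graft, los_true)
  tx$discharged <- !died_pre
  tx
}

#' Analytic truth summary for a generator configuration
#'
#' Computes, from the configuration alone (never from sampled data), the
#' true utilization-logit and graft log-hazard-ratio curves on a TTD
#' grid, the population acceptance rate, and the expected extra accepted
#' organs per TTD stratum under reference-stratum decision-making
#' ([true_counterfactual()]). Seed-invariant by construction.
#'
#' @param config a [generator_config()].
#' @param grid TTD grid in minutes.
#' @param strata list of stratum bounds for the counterfactual truth.
#' @return object of class \code{truth_summary}.
#' @export
truth_summary <- function(config, grid = 0:60,
                          strata = list(c(15, 30), c(30, 45))) {
  law <- covariate_score_law(config)
  curve <- data.frame(
    ttd = grid,
    util_logit = config$util_intercept + util_ttd_logit(grid, config),
    util_prob = expected_logistic(
      config$util_intercept + util_ttd_logit(grid, config),
      law[["mean"]], law[["sd"]]),
    graft_loghr = graft_ttd_loghr(grid, config))
  qs <- stats::qlnorm(seq(0.0005, 0.9995, by = 0.001),
                      config$ttd_meanlog, config$ttd_sdlog)
  overall <- mean(expected_logistic(
    config$util_intercept + util_ttd_logit(qs, config),
    law[["mean"]], law[["sd"]]))
  cf <- lapply(strata, function(b) true_counterfactual(config, b))
  names(cf) <- vapply(strata, function(b) paste0(b[1L], "-", b[2L]), character(1L))
  structure(list(curve = curve, overall_acceptance = overall,
                 counterfactual = cf, config = config),
            class = "truth_summary")
}

#' Analytic counterfactual truth: expected extra organs in a TTD stratum
#'
#' The expected number of additional livers that would be accepted if
#' donors in the stratum were evaluated as the reference (short-TTD)
#' stratum evaluates its offers: the integral, over the stratum's TTD
#' and covariate distribution, of the acceptance probability with the
#' TTD logit term replaced by its reference-stratum (flat) value minus
#' the actual acceptance probability, times the expected stratum size.
#' Evaluated by Gauss-Hermite quadrature over the Gaussian covariate
#' score and equal-probability quadrature over the conditional TTD law;
#' no sampling, so the result is seed-invariant.
#'
#' @param config a [generator_config()].
#' @param stratum numeric \code{c(lo, hi)} TTD bounds in minutes,
#'   half-open \code{[lo, hi)}.
#' @param n_quad quadrature points over the conditional TTD law.
#' @return list with \code{n_stratum}, \code{actual_rate},
#'   \code{counterfactual_rate}, \code{extra_organs} (rates as
#'   proportions).
#' @export
true_counterfactual <- function(config, stratum, n_quad = 512L) {
  stopifnot(length(stratum) == 2L, stratum[1L] < stratum[2L])
  p_lo <- stats::plnorm(stratum[1L], config$ttd_meanlog, config$ttd_sdlog)
  p_hi <- stats::plnorm(stratum[2L], config$ttd_meanlog, config$ttd_sdlog)
  if (p_hi - p_lo <= 0) stop("empty TTD stratum [", stratum[1L], ", ",
                             stratum[2L], ")")
  law <- covariate_score_law(config)
  u <- p_lo + (p_hi - p_lo) * (seq_len(n_quad) - 0.5) / n_quad
  t_q <- stats::qlnorm(u, config$ttd_meanlog, config$ttd_sdlog)
  actual <- mean(expected_logistic(
    config$util_intercept + util_ttd_logit(t_q, config),
    law[["mean"]], law[["sd"]]))
  cfact <- mean(expected_logistic(
    rep(config$util_intercept, n_quad), law[["mean"]], law[["sd"]]))
  n_stratum <- config$n_donors * (p_hi - p_lo)
  list(n_stratum = n_stratum, actual_rate = actual,
       counterfactual_rate = cfact,
       extra_organs = n_stratum * (cfact - actual))
}

#' Inject missing-at-random missingness
#'
#' Blanks entries of the requested variables at the requested marginal
#' rates. Missingness may depend only on always-observed variables: the
#' probability of being missing is logistic in the standardized
#' dependence variables, with the intercept calibrated (by root-finding)
#' so the marginal rate matches the request. With no dependence
#' variables the mechanism is MCAR. Requests to blank the primary
#' exposures (\code{ttd_min}, \code{asystolic_min}) are refused, since
#' donors missing those are excluded from analysis rather than imputed.
#'
#' @param records data frame.
#' @param spec named list; each element \code{list(rate, depends = NULL,
#'   strength = 1)} keyed by the variable to blank.
#' @param seed integer seed.
#' @return \code{records} with \code{NA}s injected.
#' @export
inject_missingness <- function(records, spec, seed = 1L) {
  protected <- c("ttd_min", "asystolic_min")
  bad <- intersect(names(spec), protected)
  if (length(bad)) {
    stop("refusing to inject missingness into ", paste(bad, collapse = ", "),
         ": donors with missing TTD or asystolic time are excluded from ",
         "analysis, not imputed")
  }
  set.seed(seed)
  n <- nrow(records)
  for (v in names(spec)) {
    req <- spec[[v]]
    if (!v %in% names(records)) stop("no column '", v, "' to blank")
    if (req$rate == 0) next
    if (req$rate >= 1) {
      records[[v]][] <- NA
      next
    }
    dep <- req$depends
    if (is.null(dep) || !length(dep)) {
      z <- rep(0, n)
    } else {
      if (any(vapply(records[dep], anyNA, logical(1L)))) {
        stop("MAR dependence variables must be fully observed: ",
             paste(dep, collapse = ", "))
      }
      z <- rowSums(scale(vapply(records[dep], as.numeric, numeric(n))))
    }
    strength <- if (is.null(req$strength)) 1 else req$strength
    eta <- strength * z
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + eta)) - req$rate,
      interval = c(-30, 30), tol = 1e-10)$root
    miss <- stats::runif(n) < stats::plogis(alpha + eta)
    records[[v]][miss] <- NA
  }
  records
}

#' Write a registry to delimited text
#'
#' Writes \code{donors.csv}, \code{transplants.csv} (comma-separated,
#' header row, numeric minutes/days) and \code{truth.json} into a
#' directory.
#'
#' @param registry a [generate_registry()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(registry$donors, file.path(dir, "donors.csv"),
                   row.names = FALSE)
  utils::write.csv(registry$transplants, file.path(dir, "transplants.csv"),
                   row.names = FALSE)
  if (!is.null(registry$truth)) {
    tr <- registry$truth
    jsonlite::write_json(
      list(curve = tr$curve, overall_acceptance = tr$overall_acceptance,
           counterfactual = tr$counterfactual),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a registry from delimited text
#'
#' Reads and validates the donor and transplant tables written by
#' [write_registry()] (or supplied by the user in the same schema).
#' Donor tables must carry either numeric \code{ttd_min}/
#' \code{asystolic_min} or the timestamp triple
#' \code{wlst_time}/\code{asystole_time}/\code{flush_time}
#' (ISO-8601); transplant tables must carry the donor link, survival
#' times and event indicators.
#'
#' @param dir directory containing \code{donors.csv} and
#'   \code{transplants.csv}.
#' @return list with \code{donors} and \code{transplants}.
#' @export
read_registry <- function(dir) {
  dpath <- file.path(dir, "donors.csv")
  tpath <- file.path(dir, "transplants.csv")
  for (p in c(dpath, tpath)) {
    if (!file.exists(p)) stop("missing registry file: ", p)
  }
  donors <- utils::read.csv(dpath, stringsAsFactors = FALSE)
  transplants <- utils::read.csv(tpath, stringsAsFactors = FALSE)
  has_min <- all(c("ttd_min", "asystolic_min") %in% names(donors))
  has_ts <- all(c("wlst_time", "asystole_time", "flush_time") %in% names(donors))
  if (!has_min && !has_ts) {
    stop("donor table must contain ttd_min/asystolic_min or the ",
         "wlst_time/asystole_time/flush_time timestamp triple")
  }
  if (has_ts) {
    for (cl in c("wlst_time", "asystole_time", "flush_time", "sbp50_time")) {
      if (cl %in% names(donors)) {
        donors[[cl]] <- as.POSIXct(donors[[cl]], tz = "UTC")
      }
    }
  }
  need_tx <- c("donor_id", "graft_time_days", "graft_event")
  miss <- setdiff(need_tx, names(transplants))
  if (length(miss)) {
    stop("transplant table missing required columns: ",
         paste(miss, collapse = ", "))
  }
  if (!"donor_id" %in% names(donors)) stop("donor table missing donor_id")
  list(donors = donors, transplants = transplants)
}
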