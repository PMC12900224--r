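#' Default covariate list for the graft-survival outcome model
#'
#' Transcribes the outcome-model adjustment set to the synthetic
#' registry schema: spline terms for time to death, donor age, donor
#' peak ALT, donation year and cold ischemic time; categorical donor
#' and recipient factors against stated reference levels; per-5-unit /
#' per-10-unit rescaling of BMI, age and MELD; and log2 waitlist days.
#'
#' @return list of [covariate()] treatments.
#' @export
default_outcome_covariates <- function() {
  list(
    covariate("ttd_min", "rcs"),
    covariate("pathway", "categorical", ref = "SRR"),
    covariate("donor_bmi", "linear", scale = 5),
    covariate("donor_sex", "categorical", ref = "F"),
    covariate("hypertension", "linear"),
    covariate("cause_of_death", "categorical", ref = "cerebrovascular"),
    covariate("machine_perfusion", "categorical", ref = "none"),
    covariate("recipient_age", "linear", scale = 10),
    covariate("recipient_bmi", "linear", scale = 5),
    covariate("recipient_sex", "categorical", ref = "F"),
    covariate("meld", "linear", scale = 10),
    covariate("dialysis", "linear"),
    covariate("rec_diabetes", "linear"),
    covariate("status1a", "linear"),
    covariate("diagnosis", "categorical", ref = "alcohol"),
    covariate("medical_condition", "categorical", ref = "home"),
    covariate("functional_status", "categorical", ref = "<=60"),
    covariate("ethnicity", "categorical", ref = "white"),
    covariate("waitlist_days", "log2"),
    covariate("donor_age", "rcs"),
    covariate("peak_alt", "rcs"),
    covariate("donation_year", "rcs"),
    covariate("cold_ischemic_hours", "rcs"))
}

#' Default covariate list for the utilization model
#'
#' Donor-level adjustment set for the logistic utilization model
#' (transplant-level treatments such as machine perfusion are not
#' defined for non-utilized donors and are excluded).
#'
#' @param include_ttd include the time-to-death spline (the full
#'   utilization model does; the counterfactual reference model must
#'   not).
#' @return list of [covariate()] treatments.
#' @export
default_utilization_covariates <- function(include_ttd = TRUE) {
  out <- list(
    covariate("blood_group", "categorical", ref = "A"),
    covariate("donor_bmi", "linear", scale = 5),
    covariate("donor_sex", "categorical", ref = "F"),
    covariate("hypertension", "linear"),
    covariate("diabetes", "linear"),
    covariate("cause_of_death", "categorical", ref = "cerebrovascular"),
    covariate("peak_sodium", "linear"),
    covariate("donor_age", "rcs"),
    covariate("peak_alt", "rcs"),
    covariate("peak_bilirubin", "rcs"),
    covariate("peak_albumin", "rcs"),
    covariate("donation_year", "rcs"))
  if (include_ttd) c(list(covariate("ttd_min", "rcs")), out) else out
}

#' Format a pooled fit as a publication-style results table
#'
#' One row per model term, with exponentiated estimates rendered as
#' \code{"1.000 (0.141-7.099)"}; spline and categorical blocks are
#' collapsed to a single joint Wald-test row; reference categories are
#' rendered with an em-dash P value; log2 terms are annotated "per
#' doubling".
#'
#' @param pooled a [pool_fits()] result (or single [fit_cox()] /
#'   [fit_logistic()] wrapped by [pool_fits()]).
#' @param encoding the [encode_covariates()] encoding the fit was built
#'   with (for reference-category rows); optional.
#' @param estimate_label \code{"HR"} or \code{"OR"} (column label).
#' @return data frame with columns \code{variable}, \code{estimate},
#'   \code{p}.
#' @export
render_tables <- function(pooled, encoding = NULL, estimate_label = "HR") {
  terms <- pooled$terms
  fmt_est <- function(b, lo, hi) sprintf("%.3f (%.3f-%.3f)", exp(b), exp(lo),
                                         exp(hi))
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  rows <- list()
  spline_vars <- names(pooled$spline_specs)
  fl <- if (!is.null(encoding)) encoding$factor_levels else list()
  covs <- if (!is.null(encoding)) encoding$spec$covariates else NULL
  treatments <- list()
  if (!is.null(covs)) {
    for (cv in covs) treatments[[cv$name]] <- cv$treatment
  }
  for (g in names(pooled$groups)) {
    idx <- pooled$groups[[g]]
    if (g %in% spline_vars ||
        (!is.null(treatments[[g]]) && treatments[[g]] == "rcs")) {
      gt <- pooled$group_tests[[g]]
      rows[[g]] <- data.frame(variable = paste0("RCS term: ", g),
                              estimate = "Wald test", p = fmt_p(gt$p.value))
    } else if (length(idx) > 1L || !is.null(fl[[g]])) {
      hdr <- data.frame(variable = g, estimate = "", p = "")
      ref_row <- if (!is.null(fl[[g]])) {
        data.frame(variable = paste0("  ", fl[[g]][1L]), estimate = "Ref",
                   p = "–")
      }
      lv <- terms[idx, , drop = FALSE]
      lv_rows <- data.frame(
        variable = paste0("  ", sub(paste0("^", g, "="), "", lv$term)),
        estimate = fmt_est(lv$estimate, lv$conf.low, lv$conf.high),
        p = fmt_p(lv$p.value))
      rows[[g]] <- rbind(hdr, ref_row, lv_rows)
    } else {
      tr <- terms[idx, , drop = FALSE]
      lab <- if (startsWith(tr$term, "log2_")) {
        paste0(sub("^log2_", "Log2-", tr$term), " (per doubling)")
      } else tr$term
      rows[[g]] <- data.frame(variable = lab,
                              estimate = fmt_est(tr$estimate, tr$conf.low,
                                                 tr$conf.high),
                              p = fmt_p(tr$p.value))
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- c("variable", paste0(estimate_label, " (95% CI)"), "P")
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole study on a synthetic or user-supplied
#' registry: generate (or read) the tables, inject and then impute
#' missingness, assemble the analysis cohorts, fit the pooled outcome
#' and utilization models, extract spline effect curves and
#' Kaplan-Meier data, run the counterfactual utilization analysis, and
#' write every artifact (manifest with seeds and cohort sizes, model
#' tables, effect curves, KM data, exclusion log, counterfactual
#' results) as CSV/JSON under \code{out_dir}. All randomness descends
#' from \code{seed} through fixed per-stage offsets, so reruns are
#' bit-identical.
#'
#' @param config a YAML file path, or a list, with optional elements
#'   \code{generator} (args for
#'   [generator_config()]), \code{input_dir} (read instead of
#'   generate), \code{cohort} (args for [cohort_spec()]),
#'   \code{imputation} (\code{vars}, \code{m}, \code{k_pmm}),
#'   \code{counterfactual} (\code{targets} list, \code{reps}),
#'   \code{out_dir}, \code{seed}, \code{verbose}.
#' @return list of class \code{pipeline_bundle} with all results,
#'   invisibly when \code{out_dir} is set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  verbose <- isTRUE(config$verbose)
  say <- function(...) if (verbose) message(sprintf(...))

  # --- inputs ------------------------------------------------------------
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      stop("input path does not exist: ", config$input_dir)
    }
    reg <- read_registry(config$input_dir)
    reg$truth <- NULL
    say("stage=read donors=%d transplants=%d", nrow(reg$donors),
        nrow(reg$transplants))
  } else {
    gen_args <- config$generator
    if (is.null(gen_args)) gen_args <- list()
    if (is.null(gen_args$seed)) gen_args$seed <- seed
    gcfg <- do.call(generator_config, gen_args)
    reg <- generate_registry(gcfg)
    miss_spec <- gcfg$missingness
    if (length(miss_spec)) {
      reg$donors <- inject_missingness(reg$donors, miss_spec, seed = seed + 1L)
    }
    say("stage=generate donors=%d transplants=%d", nrow(reg$donors),
        nrow(reg$transplants))
  }

  # --- cohorts -----------------------------------------------------------
  cspec <- do.call(cohort_spec,
                   if (is.null(config$cohort)) list() else config$cohort)
  cohorts <- apply_inclusion(reg$donors, reg$transplants, cspec)
  say("stage=assemble utilization=%d outcome=%d excluded_donors=%d",
      nrow(cohorts$utilization), nrow(cohorts$outcome),
      sum(unlist(cohorts$exclusion_log$donors)))

  # --- imputation --------------------------------------------------------
  icfg <- config$imputation
  m <- if (is.null(icfg$m)) 20L else icfg$m
  k_pmm <- if (is.null(icfg$k_pmm)) 3L else icfg$k_pmm
  util <- cohorts$utilization
  ivars_u <- if (is.null(icfg$vars)) {
    cand <- names(util)[vapply(util, function(v) {
      anyNA(v) && any(!is.na(v)) && (is.numeric(v) || is.logical(v))
    }, logical(1L))]
    cand
  } else icfg$vars
  ivars_u <- setdiff(ivars_u, c("ttd_min", "asystolic_min", "invalid_times"))
  util$.utilized_aux <- as.integer(util$utilized)
  util_sets <- impute_pmm(util, ivars_u, auxiliaries = ".utilized_aux",
                          m = m, k_pmm = k_pmm, seed = seed + 2L)
  say("stage=impute cohort=utilization vars=%s m=%d",
      paste(ivars_u, collapse = ","), m)

  outc <- cohorts$outcome
  outc$.graft_event_aux <- as.integer(outc$graft_event)
  outc$.graft_cumhaz_aux <- nelson_aalen(outc$graft_time_days,
                                         outc$graft_event)
  ivars_o <- intersect(ivars_u, names(outc)[vapply(outc, anyNA, logical(1L))])
  outcome_sets <- impute_pmm(outc, ivars_o,
                             auxiliaries = c(".graft_event_aux",
                                             ".graft_cumhaz_aux"),
                             m = m, k_pmm = k_pmm, seed = seed + 3L)
  say("stage=impute cohort=outcome vars=%s m=%d",
      paste(ivars_o, collapse = ","), m)

  # --- models ------------------------------------------------------------
  graft_spec <- model_spec("graft_survival_1y", "cox", time = "graft_time_days",
                           event = "graft_event",
                           covariates = default_outcome_covariates(),
                           horizon_days = 365)
  graft_fit <- run_mi_analysis(outcome_sets, graft_spec)
  say("stage=fit model=graft_survival_1y n=%d events=%d",
      graft_fit$pooled$n, graft_fit$pooled$events)

  util_spec <- model_spec("utilization", "logistic", response = "utilized",
                          covariates = default_utilization_covariates())
  util_srr <- lapply(util_sets, function(d) d[d$pathway == "SRR", , drop = FALSE])
  util_fit <- run_mi_analysis(util_srr, util_spec)
  say("stage=fit model=utilization_srr n=%d accepted=%d",
      util_fit$pooled$n, util_fit$pooled$events)

  km <- km_curve(pmin(cohorts$outcome$graft_time_days, 365),
                 ifelse(cohorts$outcome$graft_time_days > 365, 0L,
                        cohorts$outcome$graft_event),
                 stratify_ttd(cohorts$outcome$ttd_min, cspec))

  # --- counterfactual (on completed dataset 1, SRR donors) ---------------
  ccfg <- config$counterfactual
  targets <- if (is.null(ccfg$targets)) list(c(15, 30), c(30, 45)) else
    ccfg$targets
  reps <- if (is.null(ccfg$reps)) 10000L else ccfg$reps
  srr1 <- util_srr[[1L]]
  cf <- lapply(targets, function(tg) {
    counterfactual_analysis(
      srr1,
      counterfactual_spec(target = tg, reps = reps, seed = seed + 4L,
                          covariates = default_utilization_covariates(FALSE)))
  })
  names(cf) <- vapply(targets, function(tg) paste0(tg[1L], "-", tg[2L]),
                      character(1L))
  for (nm in names(cf)) {
    say("stage=counterfactual target=%s extra=%.1f", nm, cf[[nm]]$extra_organs)
  }

  bundle <- structure(
    list(seed = seed,
         truth = reg$truth,
         cohorts = list(utilization_n = nrow(cohorts$utilization),
                        outcome_n = nrow(cohorts$outcome),
                        exclusion_log = cohorts$exclusion_log),
         graft_model = graft_fit,
         utilization_model = util_fit,
         km = km,
         counterfactual = cf),
    class = "pipeline_bundle")

  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    say("stage=write out_dir=%s", config$out_dir)
  }
  invisible(bundle)
}

cf_as_list <- function(x) {
  list(reference = x$reference, target = x$target, n_target = x$n_target,
       actual_count = x$actual_count, actual_rate_pct = x$actual_rate_pct,
       predicted_rate_pct = x$predicted_rate_pct, predicted_ci = x$predicted_ci,
       absolute_pp = x$absolute_pp, absolute_ci = x$absolute_ci,
       relative_pct = x$relative_pct, relative_ci = x$relative_ci,
       extra_organs = x$extra_organs,
       extra_organs_rounded = x$extra_organs_rounded, extra_ci = x$extra_ci,
       reps = x$reps, degenerate = x$degenerate, seed = x$seed)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ver <- as.character(utils::packageVersion("dcdlivers"))
  jsonlite::write_json(
    list(seed = bundle$seed, package_version = ver,
         cohorts = bundle$cohorts[c("utilization_n", "outcome_n")],
         exclusion_log = bundle$cohorts$exclusion_log),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$cohorts$exclusion_log,
                       file.path(out_dir, "exclusion_log.json"),
                       auto_unbox = TRUE)
  utils::write.csv(render_tables(bundle$graft_model$pooled,
                                 bundle$graft_model$encoding, "HR"),
                   file.path(out_dir, "graft_model.csv"), row.names = FALSE)
  utils::write.csv(render_tables(bundle$utilization_model$pooled,
                                 bundle$utilization_model$encoding, "OR"),
                   file.path(out_dir, "utilization_model.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$graft_model$curves)) {
    write_effect_curve(bundle$graft_model$curves[[nm]],
                       file.path(out_dir, paste0("curve_graft_", nm, ".csv")))
  }
  for (nm in names(bundle$utilization_model$curves)) {
    write_effect_curve(bundle$utilization_model$curves[[nm]],
                       file.path(out_dir, paste0("curve_util_", nm, ".csv")))
  }
  utils::write.csv(bundle$km$curve, file.path(out_dir, "km_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(bundle$counterfactual, cf_as_list),
                       file.path(out_dir, "counterfactual.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
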