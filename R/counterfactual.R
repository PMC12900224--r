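#' Specification of the counterfactual utilization analysis
#'
#' Defines the reference stratum of short time-to-death (TTD) donors
#' whose acceptance behavior is taken as the counterfactual standard,
#' the target stratum of longer-TTD donors that behavior is projected
#' onto, the covariates of the TTD-free utilization model, and the
#' percentile-bootstrap settings.
#'
#' @param reference TTD bounds \code{c(lo, hi)} of the reference
#'   stratum, half-open \code{[lo, hi)}; default under 10 minutes.
#' @param target TTD bounds of the target stratum; default 15-30
#'   minutes.
#' @param covariates list of [covariate()] treatments for the
#'   utilization model. Any term in TTD is rejected: the point of the
#'   analysis is that TTD is excluded from the model.
#' @param reps bootstrap replicates (default 10000).
#' @param conf_level confidence level of the percentile intervals.
#' @param seed integer seed for the bootstrap.
#' @param max_degenerate_frac tolerated fraction of degenerate
#'   bootstrap replicates before erroring.
#' @param utilized_col name of the utilization flag column.
#' @param ttd_col name of the TTD column.
#' @return object of class \code{counterfactual_spec}.
#' @export
counterfactual_spec <- function(reference = c(0, 10), target = c(15, 30),
                                covariates = list(), reps = 10000L,
                                conf_level = 0.95, seed = 1L,
                                max_degenerate_frac = 0.05,
                                utilized_col = "utilized",
                                ttd_col = "ttd_min") {
  stopifnot(reps >= 1L, length(reference) == 2L, length(target) == 2L,
            reference[1L] < reference[2L], target[1L] < target[2L])
  if (max(reference[1L], target[1L]) < min(reference[2L], target[2L])) {
    stop("reference and target strata must be disjoint")
  }
  cn <- vapply(covariates, `[[`, character(1L), "name")
  if (any(cn == ttd_col)) {
    stop("the utilization model must exclude the TTD term ('", ttd_col,
         "'); that exclusion is the counterfactual")
  }
  structure(list(reference = reference, target = target,
                 covariates = covariates, reps = as.integer(reps),
                 conf_level = conf_level, seed = seed,
                 max_degenerate_frac = max_degenerate_frac,
                 utilized_col = utilized_col, ttd_col = ttd_col),
            class = "counterfactual_spec")
}

in_stratum <- function(ttd, bounds) {
  !is.na(ttd) & ttd >= bounds[1L] & ttd < bounds[2L]
}

#' Fit the reference-stratum utilization model
#'
#' Logistic regression for liver utilization fitted only on donors in
#' the reference (short-TTD) stratum, with TTD excluded from the
#' covariates. The fit estimates how offers are evaluated when TTD does
#' not influence the decision; by the maximum-likelihood identity its
#' mean fitted probability equals the reference stratum's observed
#' acceptance rate.
#'
#' @param donors donor data frame (utilization cohort).
#' @param spec a [counterfactual_spec()].
#' @return a [fit_logistic()] result carrying its encoding.
#' @export
fit_reference <- function(donors, spec) {
  sel <- in_stratum(donors[[spec$ttd_col]], spec$reference)
  if (!any(sel)) stop("reference stratum is empty")
  ref <- donors[sel, , drop = FALSE]
  y <- ref[[spec$utilized_col]]
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("reference stratum has a single utilization class; cannot fit")
  }
  ms <- model_spec(outcome = "utilization", type = "logistic",
                   response = spec$utilized_col, covariates = spec$covariates)
  fit_logistic(ref, ms)
}

#' Project the reference model onto a target stratum
#'
#' Standardization (G-computation): the reference-stratum model is
#' applied to every donor in the target stratum, and the predicted
#' acceptance rate is the mean of the per-donor predicted
#' probabilities. Factor levels unseen in the reference stratum are
#' assigned the reference-level effect and counted.
#'
#' @param fit a [fit_reference()] result.
#' @param target donors in the target stratum.
#' @return list with \code{predicted_rate} (proportion),
#'   \code{predicted_count}, \code{n}, \code{unseen_levels}.
#' @export
project_acceptance <- function(fit, target) {
  if (!nrow(target)) stop("target stratum is empty")
  enc <- encode_covariates(target, fit$encoding$spec, fit$encoding)
  Xi <- cbind(1, enc$X)
  keep <- stats::complete.cases(Xi)
  if (!any(keep)) stop("no complete target-stratum records to project onto")
  p <- stats::plogis(drop(Xi[keep, , drop = FALSE] %*% fit$coefficients))
  list(predicted_rate = mean(p), predicted_count = sum(p), n = sum(keep),
       unseen_levels = enc$unseen - fit$encoding$unseen)
}

#' Point estimates of the counterfactual gain
#'
#' Exact arithmetic on acceptance rates, on the percentage scale used
#' in reporting: the absolute increase is predicted minus actual (in
#' percentage points), the relative increase is the absolute increase
#' over the actual rate (as a percentage), and the extra-organ count is
#' the target stratum size times the absolute increase.
#'
#' @param actual_rate_pct observed acceptance rate in the target
#'   stratum, percent.
#' @param predicted_rate_pct counterfactual acceptance rate, percent.
#' @param n_target number of donors in the target stratum.
#' @return list with \code{absolute_pp}, \code{relative_pct} (\code{NA}
#'   when the actual rate is 0), \code{extra_organs},
#'   \code{extra_organs_rounded} (half-up).
#' @export
summarize_counterfactual <- function(actual_rate_pct, predicted_rate_pct,
                                     n_target) {
  stopifnot(n_target > 0)
  absolute <- predicted_rate_pct - actual_rate_pct
  relative <- if (actual_rate_pct > 0) 100 * absolute / actual_rate_pct else NA_real_
  extra <- n_target * absolute / 100
  list(absolute_pp = absolute, relative_pct = relative,
       extra_organs = extra, extra_organs_rounded = floor(extra + 0.5))
}

percentile_ci <- function(x, conf_level) {
  x <- sort(x[!is.na(x)])
  r <- length(x)
  a <- (1 - conf_level) / 2
  c(lower = x[max(1L, ceiling(a * r))], upper = x[ceiling((1 - a) * r)])
}

#' Counterfactual utilization analysis with percentile bootstrap
#'
#' The full "extra livers" analysis: fit the TTD-free utilization model
#' on the reference stratum, project it onto the target stratum,
#' compare predicted with actual acceptance, and attach percentile
#' bootstrap confidence intervals. Each replicate resamples donors with
#' replacement within the reference and target strata independently,
#' refits the reference model, re-projects and re-summarizes; interval
#' endpoints are the order statistics at the 2.5th/97.5th percentiles
#' of the replicate statistics. Spline knots and factor levels are held
#' at their full-data values across replicates. Replicates whose refit
#' is degenerate (single utilization class, or non-convergence) are
#' counted and dropped; more than \code{max_degenerate_frac} of them is
#' an error unless \code{allow_degenerate}.
#'
#' @param donors donor data frame (utilization cohort, one row per
#'   potential donor).
#' @param spec a [counterfactual_spec()].
#' @param allow_degenerate keep going (with a warning) when the
#'   degenerate fraction exceeds the tolerance.
#' @return object of class \code{counterfactual_result}.
#' @export
counterfactual_analysis <- function(donors, spec, allow_degenerate = FALSE) {
  ttd <- donors[[spec$ttd_col]]
  tsel <- in_stratum(ttd, spec$target)
  target <- donors[tsel, , drop = FALSE]
  if (!nrow(target)) stop("target stratum is empty")

  fit <- fit_reference(donors, spec)
  proj <- project_acceptance(fit, target)
  y_t <- as.integer(target[[spec$utilized_col]])
  actual_rate <- mean(y_t)
  n_target <- nrow(target)
  point <- summarize_counterfactual(100 * actual_rate,
                                    100 * proj$predicted_rate, n_target)

  # Bootstrap on precomputed design matrices (knots/levels fixed).
  rsel <- in_stratum(ttd, spec$reference)
  ref <- donors[rsel, , drop = FALSE]
  enc_r <- fit$encoding
  Xr <- cbind(1, enc_r$X)
  yr <- as.integer(ref[[spec$utilized_col]])
  enc_t <- encode_covariates(target, enc_r$spec, enc_r)
  Xt <- cbind(1, enc_t$X)
  nr <- nrow(Xr)

  set.seed(spec$seed)
  reps <- spec$reps
  stat <- matrix(NA_real_, reps, 4L,
                 dimnames = list(NULL, c("predicted", "absolute", "relative",
                                         "extra")))
  degenerate <- 0L
  for (r in seq_len(reps)) {
    ri <- sample.int(nr, nr, replace = TRUE)
    ti <- sample.int(n_target, n_target, replace = TRUE)
    yb <- yr[ri]
    if (all(yb == yb[1L])) { degenerate <- degenerate + 1L; next }
    fb <- tryCatch(
      suppressWarnings(stats::glm.fit(Xr[ri, , drop = FALSE], yb,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged || anyNA(fb$coefficients)) {
      degenerate <- degenerate + 1L; next
    }
    pb <- mean(stats::plogis(drop(Xt[ti, , drop = FALSE] %*% fb$coefficients)))
    ab <- mean(y_t[ti])
    s <- summarize_counterfactual(100 * ab, 100 * pb, n_target)
    stat[r, ] <- c(100 * pb, s$absolute_pp, s$relative_pct, s$extra_organs)
  }
  if (degenerate / reps > spec$max_degenerate_frac) {
    msg <- sprintf("%d of %d bootstrap replicates were degenerate",
                   degenerate, reps)
    if (allow_degenerate) warning(msg) else
      stop(msg, "; rerun with allow_degenerate = TRUE to override")
  }
  cis <- apply(stat, 2L, percentile_ci, conf_level = spec$conf_level)
  structure(
    list(n_target = n_target,
         actual_count = sum(y_t),
         actual_rate_pct = 100 * actual_rate,
         predicted_rate_pct = 100 * proj$predicted_rate,
         predicted_ci = unname(cis[, "predicted"]),
         absolute_pp = point$absolute_pp,
         absolute_ci = unname(cis[, "absolute"]),
         relative_pct = point$relative_pct,
         relative_ci = unname(cis[, "relative"]),
         extra_organs = point$extra_organs,
         extra_organs_rounded = point$extra_organs_rounded,
         extra_ci = unname(cis[, "extra"]),
         reps = reps, degenerate = degenerate, seed = spec$seed,
         unseen_levels = proj$unseen_levels,
         reference = spec$reference, target = spec$target),
    class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  fmt <- function(v, ci, d = 1) {
    sprintf(paste0("%.", d, "f (%.", d, "f-%.", d, "f)"), v, ci[1L], ci[2L])
  }
  cat(sprintf("Counterfactual utilization, TTD [%g, %g) evaluated as TTD [%g, %g)\n",
              x$target[1L], x$target[2L], x$reference[1L], x$reference[2L]))
  cat(sprintf("  donors in target stratum: %d (accepted: %d)\n",
              x$n_target, x$actual_count))
  cat(sprintf("  actual acceptance rate: %.1f%%\n", x$actual_rate_pct))
  cat(sprintf("  predicted acceptance rate: %s%%\n",
              fmt(x$predicted_rate_pct, x$predicted_ci)))
  cat(sprintf("  absolute increase: %s percentage points\n",
              fmt(x$absolute_pp, x$absolute_ci)))
  cat(sprintf("  relative increase: %s%%\n", fmt(x$relative_pct, x$relative_ci)))
  cat(sprintf("  extra organs: %s [rounded: %d]\n",
              fmt(x$extra_organs, x$extra_ci, 1), x$extra_organs_rounded))
  cat(sprintf("  bootstrap: %d replicates (%d degenerate), seed %d\n",
              x$reps, x$degenerate, x$seed))
  invisible(x)
}
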