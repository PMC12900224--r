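#' Cohort specification
#'
#' Thresholds and rules used to derive the analysis cohorts from a donor
#' registry: the adult-recipient age floor, the asystole-to-flush cut
#' that separates super-rapid recovery (SRR) from normothermic regional
#' perfusion (NRP), the length-of-stay censoring horizon, the early
#' graft loss window, the systolic-pressure threshold defining
#' functional time to death, and the time-to-death strata used in
#' reporting and the counterfactual analysis.
#'
#' @param adult_age_min minimum recipient age in years (default 18).
#' @param pathway_rule_threshold asystolic minutes above which a donor
#'   is classified NRP (default 30; 30.0 itself is SRR).
#' @param los_censor hospital length-of-stay censoring horizon in days
#'   (default 90).
#' @param early_graft_loss_window days defining early graft loss
#'   (default 30).
#' @param fttd_sbp_threshold systolic blood pressure (mm Hg) defining
#'   the start of functional time to death (default 50).
#' @param ttd_strata ordered interior bin edges, minutes; bins are
#'   half-open \code{[lo, hi)} with an overflow bin above the last edge.
#' @param inclusion_years optional two-element numeric vector of
#'   donation years retained (inclusive).
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(adult_age_min = 18,
                        pathway_rule_threshold = 30,
                        los_censor = 90,
                        early_graft_loss_window = 30,
                        fttd_sbp_threshold = 50,
                        ttd_strata = c(0, 10, 15, 30, 45),
                        inclusion_years = NULL) {
  stopifnot(adult_age_min > 0, pathway_rule_threshold > 0,
            los_censor > 0, early_graft_loss_window > 0,
            fttd_sbp_threshold > 0)
  if (any(diff(ttd_strata) <= 0)) stop("ttd_strata edges must be strictly increasing")
  structure(
    list(adult_age_min = adult_age_min,
         pathway_rule_threshold = pathway_rule_threshold,
         los_censor = los_censor,
         early_graft_loss_window = early_graft_loss_window,
         fttd_sbp_threshold = fttd_sbp_threshold,
         ttd_strata = ttd_strata,
         inclusion_years = inclusion_years),
    class = "cohort_spec")
}

#' Derive warm-ischemia intervals from timestamps or minutes
#'
#' Fills \code{ttd_min} (withdrawal of life-sustaining treatment to
#' asystole), \code{asystolic_min} (asystole to aortic cold flush) and
#' \code{fttd_min} (systolic pressure first below threshold to cold
#' flush) for every donor. Records that already carry numeric minutes
#' are passed through; records with a timestamp triple
#' \code{wlst_time <= asystole_time <= flush_time} have the minutes
#' computed by subtraction. Records with a negative interval are flagged
#' in the \code{invalid_times} column with a reason; downstream
#' assembly excludes them.
#'
#' @param donors donor data frame.
#' @return the donor data frame with \code{ttd_min}, \code{asystolic_min},
#'   \code{fttd_min}, \code{invalid_times} (character, \code{NA} if valid).
#' @export
derive_times <- function(donors) {
  n <- nrow(donors)
  mins <- function(a, b) as.numeric(difftime(b, a, units = "mins"))
  has_ts <- all(c("wlst_time", "asystole_time", "flush_time") %in% names(donors))
  if (!("ttd_min" %in% names(donors))) donors$ttd_min <- NA_real_
  if (!("asystolic_min" %in% names(donors))) donors$asystolic_min <- NA_real_
  if (!("fttd_min" %in% names(donors))) donors$fttd_min <- NA_real_
  invalid <- rep(NA_character_, n)

  if (has_ts) {
    need <- is.na(donors$ttd_min) & !is.na(donors$wlst_time) & !is.na(donors$asystole_time)
    donors$ttd_min[need] <- mins(donors$wlst_time[need], donors$asystole_time[need])
    need <- is.na(donors$asystolic_min) & !is.na(donors$asystole_time) & !is.na(donors$flush_time)
    donors$asystolic_min[need] <- mins(donors$asystole_time[need], donors$flush_time[need])
    if ("sbp50_time" %in% names(donors)) {
      need <- is.na(donors$fttd_min) & !is.na(donors$sbp50_time) & !is.na(donors$flush_time)
      donors$fttd_min[need] <- mins(donors$sbp50_time[need], donors$flush_time[need])
    }
  }
  bad_ttd <- !is.na(donors$ttd_min) & donors$ttd_min < 0
  bad_asy <- !is.na(donors$asystolic_min) & donors$asystolic_min < 0
  invalid[bad_ttd] <- "asystole before WLST"
  invalid[bad_asy & is.na(invalid)] <- "cold flush before asystole"
  donors$invalid_times <- invalid
  donors
}

#' Classify recovery pathway from asystolic time
#'
#' Donors with more than \code{threshold} minutes from asystole to cold
#' flush are classified as NRP (in-situ normothermic regional perfusion
#' ends at the cold flush, so prolonged asystole-to-flush marks NRP
#' use); those at or below the threshold are super-rapid recovery (SRR).
#' The boundary value itself is SRR. Missing asystolic time gives
#' \code{"unknown"}; such donors are excluded from pathway-stratified
#' analyses.
#'
#' @param asystolic_min asystole-to-flush interval in minutes.
#' @param threshold classification cut in minutes (default 30).
#' @return character vector: \code{"SRR"}, \code{"NRP"} or \code{"unknown"}.
#' @export
classify_pathway <- function(asystolic_min, threshold = 30) {
  out <- ifelse(asystolic_min > threshold, "NRP", "SRR")
  out[!is.finite(asystolic_min)] <- "unknown"
  out
}

#' Apply inclusion and exclusion rules
#'
#' Builds the two analysis cohorts from a registry:
#' \itemize{
#'   \item the \emph{utilization cohort}: all eligible donors, whether
#'     or not the liver was transplanted;
#'   \item the \emph{outcome cohort}: transplanted grafts with adult
#'     recipients, restricted to years with complete follow-up.
#' }
#' Exclusion rules run in a fixed order (invalid timing, uncontrolled
#' donation, missing time to death or asystolic time for donors;
#' multiorgan transplant, pediatric recipient, incomplete follow-up for
#' recipients) and every removal is counted in the exclusion log, which
#' mirrors a study flow diagram.
#'
#' @param donors donor data frame (after [derive_times()]; derived if not).
#' @param transplants transplant data frame with a \code{donor_id} link.
#' @param spec a [cohort_spec()].
#' @return list with \code{utilization} (donors), \code{outcome}
#'   (transplants joined to their donors), and \code{exclusion_log}
#'   (named integer vectors per cohort).
#' @export
apply_inclusion <- function(donors, transplants, spec = cohort_spec()) {
  if (!("invalid_times" %in% names(donors))) donors <- derive_times(donors)
  if (!("pathway" %in% names(donors)) || all(is.na(donors$pathway))) {
    donors$pathway <- classify_pathway(donors$asystolic_min,
                                       spec$pathway_rule_threshold)
  }
  dlog <- c(invalid_timing = 0L, uncontrolled = 0L, missing_ttd_asystolic = 0L,
            outside_inclusion_years = 0L)
  keep <- rep(TRUE, nrow(donors))

  drop_rule <- function(bad, rule) {
    bad <- bad & keep
    dlog[[rule]] <<- sum(bad)
    keep <<- keep & !bad
  }
  drop_rule(!is.na(donors$invalid_times), "invalid_timing")
  if ("uncontrolled" %in% names(donors)) {
    drop_rule(donors$uncontrolled %in% TRUE, "uncontrolled")
  }
  drop_rule(is.na(donors$ttd_min) | is.na(donors$asystolic_min),
            "missing_ttd_asystolic")
  if (!is.null(spec$inclusion_years) && "donation_year" %in% names(donors)) {
    drop_rule(donors$donation_year < spec$inclusion_years[1L] |
                donors$donation_year > spec$inclusion_years[2L],
              "outside_inclusion_years")
  }
  utilization <- donors[keep, , drop = FALSE]

  tlog <- c(donor_excluded = 0L, multiorgan = 0L, pediatric_recipient = 0L)
  tkeep <- rep(TRUE, nrow(transplants))
  tdrop <- function(bad, rule) {
    bad <- bad & tkeep
    tlog[[rule]] <<- sum(bad)
    tkeep <<- tkeep & !bad
  }
  tdrop(!(transplants$donor_id %in% utilization$donor_id), "donor_excluded")
  if ("multiorgan" %in% names(transplants)) {
    tdrop(transplants$multiorgan %in% TRUE, "multiorgan")
  }
  tdrop(is.na(transplants$recipient_age) |
          transplants$recipient_age < spec$adult_age_min,
        "pediatric_recipient")
  outcome <- transplants[tkeep, , drop = FALSE]
  donor_cols <- setdiff(names(utilization), names(outcome))
  outcome <- cbind(outcome,
                   utilization[match(outcome$donor_id, utilization$donor_id),
                               donor_cols, drop = FALSE])
  rownames(outcome) <- NULL
  list(utilization = utilization, outcome = outcome,
       exclusion_log = list(donors = as.list(dlog), transplants = as.list(tlog)))
}

#' Censor hospital length of stay
#'
#' Length of stay is analyzed as time-to-discharge: discharge is the
#' event, and stays are censored at a maximum horizon (default 90 days)
#' for patients still in hospital, or at the time of death or graft loss
#' when that occurs before discharge.
#'
#' @param los_days days from transplant to discharge (or to the end of
#'   observation if not discharged); nonnegative.
#' @param discharged logical, was the patient discharged alive with
#'   graft intact at \code{los_days}.
#' @param died_or_lost_before_discharge logical, did death or graft loss
#'   end the stay before discharge.
#' @param spec a [cohort_spec()] (uses \code{los_censor}).
#' @return data frame with \code{time} (days, capped at the horizon) and
#'   \code{event} (1 = discharged, 0 = censored).
#' @export
censor_los <- function(los_days, discharged,
                       died_or_lost_before_discharge = !discharged,
                       spec = cohort_spec()) {
  if (any(los_days < 0, na.rm = TRUE)) stop("los_days must be nonnegative")
  event <- as.integer(discharged & !died_or_lost_before_discharge)
  time <- los_days
  over <- !is.na(time) & time > spec$los_censor
  time[over] <- spec$los_censor
  event[over] <- 0L
  data.frame(time = time, event = event)
}

#' Assign time-to-death strata
#'
#' Bins time to death into half-open intervals \code{[lo, hi)} defined
#' by the spec's edges, with an overflow bin above the last edge. A
#' shared endpoint belongs to the upper stratum, so 15.0 min falls in
#' "15-30", not "10-15".
#'
#' @param ttd_min time to death in minutes.
#' @param spec a [cohort_spec()] (uses \code{ttd_strata}).
#' @return factor of stratum labels such as \code{"<10"}, \code{"15-30"},
#'   \code{">=45"}.
#' @export
stratify_ttd <- function(ttd_min, spec = cohort_spec()) {
  edges <- spec$ttd_strata
  labs <- character(length(edges))
  labs[1L] <- paste0("<", edges[2L])
  if (length(edges) > 2L) {
    for (i in 2:(length(edges) - 1L)) {
      labs[i] <- paste0(edges[i], "-", edges[i + 1L])
    }
  }
  labs[length(edges)] <- paste0(">=", edges[length(edges)])
  idx <- findInterval(ttd_min, edges, left.open = FALSE, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L   # below the first edge: lowest stratum
  factor(labs[idx], levels = labs)
}
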