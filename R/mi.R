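#' Nelson-Aalen cumulative hazard at each record's time
#'
#' Step-function estimate \eqn{\hat H(t) = \sum_{t_i \le t} d_i / n_i}
#' over the distinct event times, evaluated at every record's own
#' follow-up time. Used as the outcome-aware auxiliary variable in the
#' imputation model for survival outcomes, alongside the event
#' indicator, so that imputed covariates preserve their relationship
#' with the outcome.
#'
#' @param time nonnegative follow-up times.
#' @param event event indicators (0/1 or logical).
#' @return numeric vector of \eqn{\hat H} at each record's time.
#' @export
nelson_aalen <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time < 0, na.rm = TRUE)) stop("times must be nonnegative")
  event <- as.integer(event)
  et <- sort(unique(time[event == 1L]))
  if (!length(et)) return(rep(0, length(time)))
  d <- vapply(et, function(t) sum(time == t & event == 1L), numeric(1L))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1L))
  H <- cumsum(d / n_risk)
  idx <- findInterval(time, et)
  ifelse(idx == 0L, 0, H[pmax(idx, 1L)])
}

# Design matrix for the internal imputation models: restricted cubic
# splines (3 knots) for rich continuous predictors, linear terms
# otherwise, dummies for categoricals. Missing predictor values are
# filled with the observed median/mode (simplification; the targets'
# own missingness is what PMM handles).
imputation_design <- function(data, predictors) {
  cols <- list()
  for (p in predictors) {
    x <- data[[p]]
    if (all(is.na(x))) next
    if (is.logical(x)) x <- as.numeric(x)
    if (is.numeric(x)) {
      if (anyNA(x)) x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      if (length(unique(x)) >= 7L) {
        kn <- tryCatch(compute_knots(x, c(10, 50, 90)), error = function(e) NULL)
        if (!is.null(kn)) {
          cols[[p]] <- rcs_basis(x, spline_spec(p, kn))
          next
        }
      }
      cols[[p]] <- matrix(x, ncol = 1L, dimnames = list(NULL, p))
    } else {
      x <- as.character(x)
      if (anyNA(x)) {
        tab <- table(x)
        x[is.na(x)] <- names(tab)[which.max(tab)]
      }
      lv <- sort(unique(x))
      if (length(lv) > 1L) {
        d <- vapply(lv[-1L], function(l) as.numeric(x == l),
                    numeric(nrow(data)))
        colnames(d) <- paste0(p, lv[-1L])
        cols[[p]] <- d
      }
    }
  }
  cbind(`(Intercept)` = 1, do.call(cbind, cols))
}

# Draw one PMM donor per missing entry: among the k observed rows with
# predictions closest to the missing row's prediction, pick uniformly.
pmm_draw <- function(pred_miss, pred_obs, values_obs, k) {
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  vo <- values_obs[ord]
  n_obs <- length(po)
  k <- min(k, n_obs)
  out <- vector(mode = class(vo), length(pred_miss))
  pos <- findInterval(pred_miss, po)
  for (i in seq_along(pred_miss)) {
    lo <- max(1L, pos[i] - k)
    hi <- min(n_obs, pos[i] + k)
    win <- lo:hi
    d <- abs(po[win] - pred_miss[i])
    cand <- win[order(d)[seq_len(k)]]
    out[i] <- vo[sample(cand, 1L)]
  }
  out
}

#' Multiple imputation by predictive mean matching
#'
#' Generates \code{m} completed datasets. For each imputation and each
#' target variable, the predictive model is refit on a bootstrap
#' resample of the rows with the target observed — an additive model
#' with restricted cubic spline terms for continuous predictors plus
#' the supplied outcome auxiliaries — and every missing entry is filled
#' by drawing from the \code{k_pmm} observed rows whose predictions are
#' closest to the missing row's prediction. Imputed values therefore
#' always lie in the observed support of their variable, and the
#' bootstrap step propagates model uncertainty between imputations.
#'
#' Targets may be numeric, logical, or two-level categorical; richer
#' categorical targets are not supported by this matching scheme.
#' The primary exposures \code{ttd_min} and \code{asystolic_min} are
#' never imputed (records missing them are excluded upstream).
#'
#' @param data data frame with missing entries.
#' @param vars character vector of variables to impute.
#' @param predictors character vector of predictor columns; defaults to
#'   all columns except the targets, identifiers, and auxiliaries.
#' @param auxiliaries fully observed outcome-aware columns to add to the
#'   predictive model (e.g. the event indicator and Nelson-Aalen
#'   cumulative hazard, or the utilization flag).
#' @param m number of imputations (default 20).
#' @param k_pmm matching-set size (default 3).
#' @param seed integer seed.
#' @return list of \code{m} completed data frames.
#' @export
impute_pmm <- function(data, vars, predictors = NULL, auxiliaries = character(),
                       m = 20L, k_pmm = 3L, seed = 1L) {
  stopifnot(m >= 2L, k_pmm >= 1L)
  if (any(c("ttd_min", "asystolic_min") %in% vars)) {
    stop("ttd_min and asystolic_min are never imputed; records missing ",
         "them are excluded from analysis")
  }
  if (is.null(predictors)) {
    predictors <- setdiff(names(data),
                          c(vars, auxiliaries, grep("_id$", names(data), value = TRUE)))
  }
  for (a in auxiliaries) {
    if (anyNA(data[[a]])) stop("auxiliary '", a, "' must be fully observed")
  }
  vars <- vars[vapply(vars, function(v) anyNA(data[[v]]), logical(1L))]
  if (!length(vars)) return(replicate(m, data, simplify = FALSE))
  for (v in vars) {
    x <- data[[v]]
    if (!any(!is.na(x))) stop("variable '", v, "' has no observed values")
    if (!is.numeric(x) && !is.logical(x) &&
        length(unique(x[!is.na(x)])) > 2L) {
      stop("variable '", v, "' is categorical with more than two levels; ",
           "this matching scheme imputes numeric, logical or binary variables")
    }
  }
  set.seed(seed)
  X <- imputation_design(data, c(setdiff(predictors, vars), auxiliaries))

  out <- vector("list", m)
  for (im in seq_len(m)) {
    completed <- data
    for (v in vars) {
      y <- data[[v]]
      obs <- which(!is.na(y))
      mis <- which(is.na(y))
      yv <- y[obs]
      if (is.factor(yv)) yv <- as.character(yv)
      ynum <- if (is.numeric(yv)) yv else as.numeric(factor(yv))
      boot <- sample(obs, length(obs), replace = TRUE)
      fit <- stats::lm.fit(X[boot, , drop = FALSE], ynum[match(boot, obs)])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(X %*% beta)
      completed[[v]][mis] <- pmm_draw(pred[mis], pred[obs], yv, k_pmm)
    }
    out[[im]] <- completed
  }
  out
}

#' Pool model fits across imputed datasets (Rubin's rules)
#'
#' Combines per-imputation coefficient vectors and covariance matrices:
#' the pooled coefficient is the mean; the pooled covariance is
#' \eqn{W + (1 + 1/m) B} with \eqn{W} the mean within-imputation
#' covariance and \eqn{B} the between-imputation sample covariance of
#' the coefficients. Per-term Wald statistics use large-sample normal
#' reference distributions, and group (spline or categorical block)
#' tests are computed from the pooled coefficients and pooled
#' covariance.
#'
#' @param fits list of fits, each with \code{$coefficients},
#'   \code{$vcov} and optionally \code{$groups} (e.g. [fit_cox()] or
#'   [fit_logistic()] results).
#' @param conf_level confidence level for per-term intervals.
#' @return object of class \code{pooled_fit} with elements
#'   \code{coefficients}, \code{vcov}, \code{W}, \code{B}, \code{m},
#'   \code{groups}, \code{terms} (per-term table), \code{group_tests}.
#' @export
pool_fits <- function(fits, conf_level = 0.95) {
  m <- length(fits)
  stopifnot(m >= 1L)
  nms <- names(fits[[1L]]$coefficients)
  for (i in seq_along(fits)) {
    if (!identical(names(fits[[i]]$coefficients), nms)) {
      stop("fit ", i, " has mismatched terms; cannot pool")
    }
  }
  est <- vapply(fits, function(f) unname(f$coefficients), numeric(length(nms)))
  est <- matrix(est, nrow = length(nms))
  qbar <- rowMeans(est)
  W <- Reduce(`+`, lapply(fits, function(f) unname(as.matrix(f$vcov)))) / m
  B <- if (m > 1L) stats::cov(t(est)) else matrix(0, length(nms), length(nms))
  Tv <- W + (1 + 1 / m) * B
  dimnames(Tv) <- dimnames(W) <- dimnames(B) <- list(nms, nms)
  names(qbar) <- nms
  se <- sqrt(diag(Tv))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(
    term = nms, estimate = qbar, se = se,
    statistic = qbar / se,
    p.value = 2 * stats::pnorm(-abs(qbar / se)),
    conf.low = qbar - z * se, conf.high = qbar + z * se,
    row.names = NULL)
  groups <- fits[[1L]]$groups
  group_tests <- NULL
  if (!is.null(groups)) {
    group_tests <- lapply(groups, function(idx) {
      if (length(idx) < 1L) return(NULL)
      wald_group_test(qbar[idx], Tv[idx, idx, drop = FALSE])
    })
    group_tests <- group_tests[!vapply(group_tests, is.null, logical(1L))]
  }
  structure(
    list(coefficients = qbar, vcov = Tv, W = W, B = B, m = m,
         groups = groups, terms = terms, group_tests = group_tests,
         n = fits[[1L]]$n, events = fits[[1L]]$events,
         type = fits[[1L]]$type, spline_specs = fits[[1L]]$spline_specs),
    class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("Pooled fit over", x$m, "imputation(s);", length(x$coefficients),
      "terms\n")
  print(x$terms, digits = 4)
  if (length(x$group_tests)) {
    cat("Group Wald tests:\n")
    for (g in names(x$group_tests)) {
      gt <- x$group_tests[[g]]
      cat(sprintf("  %s: chi2 = %.3f, df = %d, p = %.4g\n",
                  g, gt$statistic, gt$df, gt$p.value))
    }
  }
  invisible(x)
}
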