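#' Covariate treatment for a model specification
#'
#' Describes how one covariate enters a model: untransformed linear
#' (optionally rescaled, e.g. per 5 units), as a restricted cubic
#' spline, log2-transformed (effects are then per doubling of the
#' predictor), or as a categorical variable dummy-coded against a
#' stated reference level.
#'
#' @param name column name.
#' @param treatment one of \code{"linear"}, \code{"rcs"}, \code{"log2"},
#'   \code{"categorical"}.
#' @param scale for linear terms: units per coefficient (e.g. 5 gives a
#'   per-5-unit effect).
#' @param percentiles for rcs terms: knot percentiles (default
#'   5/35/65/95).
#' @param knots for rcs terms: explicit knots (overrides percentiles).
#' @param x_ref for rcs terms: reference value for effect curves;
#'   defaults to the first knot.
#' @param ref for categorical terms: reference level (must exist in the
#'   data).
#' @param offset for log2 terms: value added before the transform. The
#'   default 0 makes nonpositive values a hard error.
#' @return list of class \code{covariate_spec}.
#' @export
covariate <- function(name, treatment = c("linear", "rcs", "log2", "categorical"),
                      scale = 1, percentiles = c(5, 35, 65, 95), knots = NULL,
                      x_ref = NULL, ref = NULL, offset = 0) {
  treatment <- match.arg(treatment)
  structure(list(name = name, treatment = treatment, scale = scale,
                 percentiles = percentiles, knots = knots, x_ref = x_ref,
                 ref = ref, offset = offset),
            class = "covariate_spec")
}

#' Model specification
#'
#' @param outcome outcome name (for labeling).
#' @param type \code{"cox"} (time-to-event) or \code{"logistic"}
#'   (binary).
#' @param time,event column names of follow-up time and event indicator
#'   (cox) .
#' @param response column name of the binary response (logistic).
#' @param covariates list of [covariate()] treatments; each covariate
#'   may appear once.
#' @param interactions list of character pairs; each pair's encoded
#'   blocks are multiplied elementwise.
#' @param horizon_days follow-up truncation in days (e.g. 365 for 1-y
#'   analyses); \code{NULL} for none.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(outcome, type = c("cox", "logistic"), time = NULL,
                       event = NULL, response = NULL, covariates = list(),
                       interactions = list(), horizon_days = NULL) {
  type <- match.arg(type)
  nms <- vapply(covariates, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("covariates listed more than once: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (type == "cox" && (is.null(time) || is.null(event))) {
    stop("cox models need 'time' and 'event' columns")
  }
  if (type == "logistic" && is.null(response)) {
    stop("logistic models need a 'response' column")
  }
  structure(list(outcome = outcome, type = type, time = time, event = event,
                 response = response, covariates = covariates,
                 interactions = interactions, horizon_days = horizon_days),
            class = "model_spec")
}

#' Encode covariates into a design matrix with term grouping
#'
#' Expands each covariate per its treatment: rcs covariates via
#' [rcs_basis()] (knots computed from the supplied data unless fixed in
#' the treatment or reused from a previous encoding), categorical
#' covariates dummy-coded against their reference level, log2
#' covariates transformed (nonpositive values are an error unless an
#' offset is configured), and interactions as elementwise products of
#' the encoded blocks. Passing a previous \code{encoding} reuses its
#' knots and factor levels, which is how imputed datasets share one
#' basis and how counterfactual projection applies a fitted model to
#' new donors (unseen factor levels then map to the reference level and
#' are counted).
#'
#' @param data data frame.
#' @param spec a [model_spec()].
#' @param encoding optional encoding from an earlier call, for reuse.
#' @return list of class \code{encoding}: \code{X} (matrix, no
#'   intercept), \code{groups} (term name to column indices),
#'   \code{spline_specs}, \code{factor_levels}, \code{unseen} (count of
#'   unseen-level assignments), \code{spec}.
#' @export
encode_covariates <- function(data, spec, encoding = NULL) {
  blocks <- list()
  spline_specs <- if (is.null(encoding)) list() else encoding$spline_specs
  factor_levels <- if (is.null(encoding)) list() else encoding$factor_levels
  unseen <- 0L
  for (cv in spec$covariates) {
    x <- data[[cv$name]]
    if (is.null(x)) stop("no column '", cv$name, "' in data")
    blk <- switch(
      cv$treatment,
      linear = {
        m <- matrix(as.numeric(x) / cv$scale, ncol = 1L)
        colnames(m) <- cv$name
        m
      },
      log2 = {
        xx <- as.numeric(x) + cv$offset
        if (any(xx <= 0, na.rm = TRUE)) {
          stop("nonpositive values in log2 covariate '", cv$name,
               "'; set a positive 'offset' in its covariate() treatment ",
               "if that is acceptable")
        }
        m <- matrix(log2(xx), ncol = 1L)
        colnames(m) <- paste0("log2_", cv$name)
        m
      },
      rcs = {
        ss <- spline_specs[[cv$name]]
        if (is.null(ss)) {
          kn <- if (!is.null(cv$knots)) cv$knots else
            compute_knots(as.numeric(x), cv$percentiles)
          xr <- if (!is.null(cv$x_ref)) cv$x_ref else kn[1L]
          rng <- stats::quantile(as.numeric(x), c(0.01, 0.99), na.rm = TRUE,
                                 type = 7)
          ss <- spline_spec(cv$name, kn, x_ref = xr,
                            percentiles = cv$percentiles,
                            x_range = unname(rng))
          spline_specs[[cv$name]] <- ss
        }
        rcs_basis(as.numeric(x), ss)
      },
      categorical = {
        x <- as.character(x)
        lv <- factor_levels[[cv$name]]
        if (is.null(lv)) {
          lv <- unique(x[!is.na(x)])
          ref <- if (!is.null(cv$ref)) cv$ref else sort(lv)[1L]
          if (!ref %in% lv) {
            stop("reference level '", ref, "' not present in '", cv$name, "'")
          }
          lv <- c(ref, sort(setdiff(lv, ref)))
          factor_levels[[cv$name]] <- lv
        }
        new <- !is.na(x) & !(x %in% lv)
        unseen <- unseen + sum(new)
        x[new] <- lv[1L]                # unseen level -> reference
        m <- vapply(lv[-1L], function(l) as.numeric(x == l),
                    numeric(nrow(data)))
        m <- matrix(m, nrow = nrow(data))
        colnames(m) <- paste0(cv$name, "=", lv[-1L])
        m
      })
    blocks[[cv$name]] <- blk
  }
  for (ia in spec$interactions) {
    a <- blocks[[ia[1L]]]; b <- blocks[[ia[2L]]]
    if (is.null(a) || is.null(b)) {
      stop("interaction refers to unknown covariate: ",
           paste(ia, collapse = " x "))
    }
    prod <- do.call(cbind, lapply(seq_len(ncol(a)), function(i) {
      m <- a[, i] * b
      colnames(m) <- paste0(colnames(a)[i], ":", colnames(b))
      m
    }))
    blocks[[paste(ia, collapse = ":")]] <- prod
  }
  X <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow(data), 0L)
  groups <- list()
  at <- 0L
  for (nm in names(blocks)) {
    groups[[nm]] <- at + seq_len(ncol(blocks[[nm]]))
    at <- at + ncol(blocks[[nm]])
  }
  structure(list(X = X, groups = groups, spline_specs = spline_specs,
                 factor_levels = factor_levels, unseen = unseen, spec = spec),
            class = "encoding")
}

rows_complete <- function(X) {
  if (!ncol(X)) return(rep(TRUE, nrow(X)))
  stats::complete.cases(X)
}

check_design <- function(X) {
  cc <- stats::complete.cases(X)
  v <- apply(X[cc, , drop = FALSE], 2L, stats::var)
  if (any(v == 0)) {
    stop("constant covariate column(s) after encoding: ",
         paste(colnames(X)[v == 0], collapse = ", "))
  }
}

#' Multivariable Cox proportional hazards fit
#'
#' Fits the Cox partial likelihood with the Efron approximation for
#' tied event times (registry survival data have day granularity, so
#' ties are the norm). Follow-up is administratively truncated at the
#' spec's horizon before fitting, implementing 1-year / 5-year
#' analyses. Hazard ratios are \code{exp(coefficients)}.
#'
#' @param data data frame.
#' @param spec a [model_spec()] with \code{type = "cox"}.
#' @param encoding optional [encode_covariates()] result to reuse.
#' @return list of class \code{dcd_fit}: \code{coefficients},
#'   \code{vcov}, \code{groups}, \code{n}, \code{events},
#'   \code{converged}, \code{monotone_likelihood} flag,
#'   \code{spline_specs}, \code{encoding}.
#' @export
fit_cox <- function(data, spec, encoding = NULL) {
  stopifnot(inherits(spec, "model_spec"), spec$type == "cox")
  enc <- encode_covariates(data, spec, encoding)
  time <- as.numeric(data[[spec$time]])
  event <- as.integer(data[[spec$event]])
  if (!is.null(spec$horizon_days)) {
    over <- !is.na(time) & time > spec$horizon_days
    event[over] <- 0L
    time[over] <- spec$horizon_days
  }
  keep <- rows_complete(enc$X) & !is.na(time) & !is.na(event)
  X <- enc$X[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (sum(event) < 1L) stop("no events in the analysis data; cannot fit")
  if (!ncol(X)) stop("a Cox model needs at least one covariate")
  check_design(X)
  fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = "efron")
  if (is.na(fit$iter) || any(is.na(fit$coefficients))) {
    stop("Cox fit failed to produce finite coefficients")
  }
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  mono <- any(abs(beta) > 15)
  if (mono) warning("possible monotone partial likelihood (separation-like); ",
                    "coefficient(s) very large")
  structure(list(coefficients = beta, vcov = V, groups = enc$groups,
                 n = nrow(X), events = sum(event),
                 converged = TRUE, monotone_likelihood = mono,
                 type = "cox", spline_specs = enc$spline_specs,
                 encoding = enc),
            class = "dcd_fit")
}

#' Multivariable logistic regression fit
#'
#' Maximum-likelihood logistic fit; odds ratios are
#' \code{exp(coefficients)}. Perfect or quasi-separation is flagged
#' (very large coefficients or fitted probabilities at the boundary).
#'
#' @inheritParams fit_cox
#' @param spec a [model_spec()] with \code{type = "logistic"}.
#' @return list of class \code{dcd_fit} (see [fit_cox()]); the first
#'   coefficient is the intercept and \code{groups} index the remaining
#'   terms.
#' @export
fit_logistic <- function(data, spec, encoding = NULL) {
  stopifnot(inherits(spec, "model_spec"), spec$type == "logistic")
  enc <- encode_covariates(data, spec, encoding)
  y <- data[[spec$response]]
  if (is.logical(y)) y <- as.integer(y)
  keep <- rows_complete(enc$X) & !is.na(y)
  X <- enc$X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop("outcome '", spec$response, "' has a single class; cannot fit")
  }
  if (ncol(X)) check_design(X)
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::glm.fit(Xi, y, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge")
  beta <- fit$coefficients
  aliased <- is.na(beta)
  if (any(aliased)) {
    stop("aliased terms in logistic fit: ",
         paste(colnames(Xi)[aliased], collapse = ", "))
  }
  w <- fit$weights
  V <- solve(crossprod(Xi * sqrt(w)))
  dimnames(V) <- list(colnames(Xi), colnames(Xi))
  sep <- any(abs(beta[-1L]) > 15) ||
    all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (sep) warning("possible separation in logistic fit")
  groups <- lapply(enc$groups, function(idx) idx + 1L)
  structure(list(coefficients = beta, vcov = V, groups = groups,
                 n = nrow(Xi), events = sum(y),
                 converged = fit$converged, separation = sep,
                 type = "logistic", spline_specs = enc$spline_specs,
                 encoding = enc),
            class = "dcd_fit")
}

#' Kaplan-Meier curves with number-at-risk table
#'
#' Product-limit survival estimates per group, plus the number at risk
#' at stated tick times, for crude survival displays stratified by
#' (for example) time-to-death stratum.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group group labels (single group if omitted).
#' @param ticks times at which to tabulate the number at risk.
#' @return list with \code{curve} (group, time, n.risk, n.event, surv)
#'   and \code{at_risk} (group x tick table).
#' @export
km_curve <- function(time, event, group = NULL, ticks = NULL) {
  if (any(time < 0, na.rm = TRUE)) stop("times must be nonnegative")
  if (is.null(group)) group <- rep("all", length(time))
  df <- data.frame(time = time, event = as.integer(event),
                   group = as.character(group))
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(sf$strata)) {
    rep(unique(df$group), length(sf$time))
  } else {
    rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  curve <- data.frame(group = strata, time = sf$time, n.risk = sf$n.risk,
                      n.event = sf$n.event, surv = sf$surv)
  if (is.null(ticks)) ticks <- pretty(c(0, max(df$time, na.rm = TRUE)), 6)
  at_risk <- do.call(rbind, lapply(split(df, df$group), function(g) {
    vapply(ticks, function(tk) sum(g$time >= tk), numeric(1L))
  }))
  colnames(at_risk) <- ticks
  list(curve = curve, at_risk = at_risk)
}

#' Fit a model on every imputed dataset and pool
#'
#' Runs the full multiple-imputation analysis for one model: the
#' covariate encoding (spline knots, factor levels) is realized on the
#' first completed dataset and shared by all fits so that terms align,
#' each dataset is fitted, results are pooled by Rubin's rules, joint
#' Wald tests are computed for every term group, and effect curves are
#' extracted for every spline covariate. A failure on any single
#' dataset aborts with that dataset's index — silently dropping
#' imputations would bias the pooled result.
#'
#' @param datasets list of completed data frames ([impute_pmm()]).
#' @param spec a [model_spec()].
#' @param curve_grid optional named list of grids for the effect curves.
#' @return list of class \code{mi_analysis}: \code{pooled}
#'   ([pool_fits()]), \code{curves} (named list of [effect_curve()]s),
#'   \code{encoding}, \code{m}.
#' @export
run_mi_analysis <- function(datasets, spec, curve_grid = list()) {
  stopifnot(length(datasets) >= 1L)
  enc <- encode_covariates(datasets[[1L]], spec)
  fitter <- if (spec$type == "cox") fit_cox else fit_logistic
  fits <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    fits[[i]] <- tryCatch(
      fitter(datasets[[i]], spec, encoding = enc),
      error = function(e) {
        stop("model fit failed on imputed dataset ", i, ": ",
             conditionMessage(e), call. = FALSE)
      })
  }
  pooled <- pool_fits(fits)
  curves <- list()
  for (nm in names(enc$spline_specs)) {
    curves[[nm]] <- effect_curve(
      pooled, enc$spline_specs[[nm]], grid = curve_grid[[nm]],
      scale = if (spec$type == "cox") "hazard" else "odds")
  }
  structure(list(pooled = pooled, curves = curves, encoding = enc,
                 m = length(datasets)),
            class = "mi_analysis")
}
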