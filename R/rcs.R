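#' Restricted cubic spline specification
#'
#' Describes how one continuous predictor is expanded as a restricted
#' (natural) cubic spline: the knot locations, the reference value used
#' when effect curves are drawn, and the basis convention.
#'
#' With \code{k} knots the basis has \code{k - 1} columns: the variable
#' itself plus \code{k - 2} normalized truncated-cubic terms. The implied
#' function space is linear beyond the boundary knots.
#'
#' @param variable name of the predictor (character scalar).
#' @param knots strictly increasing numeric vector of knot locations
#'   (at least 3).
#' @param x_ref reference value for effect curves; defaults to the first
#'   knot.
#' @param percentiles the percentiles the knots were taken at, if any
#'   (metadata only).
#' @param x_range observed range of the training values, used to flag
#'   extrapolation in [effect_curve()]; optional.
#' @return an object of class \code{spline_spec}.
#' @seealso [compute_knots()], [rcs_basis()], [effect_curve()]
#' @export
spline_spec <- function(variable, knots, x_ref = knots[1L],
                        percentiles = NULL, x_range = NULL) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) {
    stop("at least 3 knots are required, got ", length(knots))
  }
  if (any(!is.finite(knots)) || any(diff(knots) <= 0)) {
    stop("knots must be finite and strictly increasing")
  }
  structure(
    list(variable = as.character(variable)[1L],
         knots = knots,
         x_ref = as.numeric(x_ref)[1L],
         percentiles = percentiles,
         x_range = x_range,
         basis = "truncated-power, nonlinear terms / (t_k - t_1)^2"),
    class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Restricted cubic spline for '", x$variable, "'\n", sep = "")
  cat("  knots:", paste(signif(x$knots, 6), collapse = ", "), "\n")
  cat("  reference value:", signif(x$x_ref, 6), "\n")
  invisible(x)
}

#' Knot locations at sample percentiles
#'
#' Computes spline knots as sample percentiles of the observed predictor
#' values, using linear interpolation between order statistics
#' (\code{\link[stats]{quantile}} type 7). The default percentiles
#' 5/35/65/95 give the standard 4-knot layout for registry-scale data.
#'
#' @param x numeric values; missing values are dropped.
#' @param percentiles percentiles in (0, 100), strictly increasing.
#' @return numeric vector of knots, strictly increasing.
#' @export
compute_knots <- function(x, percentiles = c(5, 35, 65, 95)) {
  x <- x[is.finite(x)]
  k <- length(percentiles)
  if (k < 3L) stop("need at least 3 percentiles")
  if (any(diff(percentiles) <= 0)) stop("percentiles must be strictly increasing")
  if (length(unique(x)) < k) {
    stop("fewer than ", k, " distinct finite values; cannot place ", k,
         " knots - use fewer knots")
  }
  kn <- unname(stats::quantile(x, percentiles / 100, type = 7))
  if (any(diff(kn) <= 0)) {
    stop("ties in the data collapse the requested knots (",
         paste(signif(kn, 6), collapse = ", "),
         "); use fewer knots or different percentiles")
  }
  kn
}

#' Restricted cubic spline basis matrix
#'
#' Expands a predictor into the truncated-power restricted cubic spline
#' basis: column 1 is the variable itself and columns
#' \code{2..k-1} are the nonlinear terms
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'        + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2}
#' for \eqn{j = 1, \dots, k-2}. The division by \eqn{(t_k-t_1)^2} keeps
#' all coefficients on the scale of \code{x}. The implied function is
#' linear for \eqn{x \le t_1} and \eqn{x \ge t_k}, with continuous value,
#' first and second derivatives everywhere.
#'
#' Missing values propagate to whole rows of missing values; imputation
#' is expected to have happened upstream.
#'
#' @param x numeric vector.
#' @param spec a [spline_spec()], or a numeric knot vector.
#' @return numeric matrix with \code{length(x)} rows and \code{k - 1}
#'   columns, named \code{<var>} and \code{<var>'}, \code{<var>''}, ...
#' @export
rcs_basis <- function(x, spec) {
  if (is.numeric(spec)) spec <- spline_spec("x", spec)
  t <- spec$knots
  k <- length(t)
  norm <- (t[k] - t[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    out[, j + 1L] <- (pos3(x - t[j]) -
                        pos3(x - t[k - 1L]) * (t[k] - t[j]) / (t[k] - t[k - 1L]) +
                        pos3(x - t[k]) * (t[k - 1L] - t[j]) / (t[k] - t[k - 1L])) / norm
  }
  colnames(out) <- paste0(spec$variable,
                          vapply(seq_len(k - 1L) - 1L,
                                 function(i) paste(rep("'", i), collapse = ""),
                                 character(1L)))
  out
}

#' Joint Wald test of a coefficient block
#'
#' Tests whether a group of coefficients (typically the columns of one
#' spline expansion, or the dummies of one categorical variable) is
#' jointly zero: statistic \eqn{\beta^T V^{-1} \beta} against a
#' chi-square with as many degrees of freedom as coefficients.
#'
#' @param beta coefficient subvector.
#' @param V covariance submatrix for \code{beta} (symmetric positive
#'   definite).
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
wald_group_test <- function(beta, V) {
  beta <- as.numeric(beta)
  V <- as.matrix(V)
  if (nrow(V) != length(beta) || ncol(V) != length(beta)) {
    stop("covariance dimensions do not match the coefficient block")
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    bad <- colnames(V)
    stop("covariance submatrix is singular; aliased terms: ",
         if (is.null(bad)) "unnamed" else paste(bad, collapse = ", "))
  }
  stat <- drop(crossprod(backsolve(ch, beta, transpose = TRUE)))
  list(statistic = stat, df = length(beta),
       p.value = stats::pchisq(stat, df = length(beta), lower.tail = FALSE))
}

#' Spline effect curve relative to a reference value
#'
#' Extracts, from a fitted model containing a spline block, the hazard or
#' odds ratio at each grid value relative to the spline's reference
#' value. The log-ratio at x is \code{(basis(x) - basis(x_ref)) %*% beta}
#' over the spline block; its variance comes from the delta method with
#' the same contrast vector, and 95% bounds are
#' \code{exp(log-ratio +/- 1.96 se)}.
#'
#' Because all other model terms enter additively they cancel in the
#' contrast, so only the spline block's coefficients and covariance are
#' needed.
#'
#' @param fit a fitted or pooled model (anything with \code{$coefficients},
#'   \code{$vcov} and a \code{$groups} list mapping group name to column
#'   indices), e.g. a [pool_fits()] or [fit_cox()] result.
#' @param spec the [spline_spec()] used when the model was encoded.
#' @param grid predictor values at which to evaluate the curve; defaults
#'   to 101 points spanning the knot range.
#' @param scale \code{"hazard"} or \code{"odds"} (annotation only).
#' @param conf_level confidence level for the bounds.
#' @return data frame of class \code{effect_curve} with columns \code{x},
#'   \code{ratio}, \code{lower}, \code{upper}, \code{extrapolated}.
#' @export
effect_curve <- function(fit, spec, grid = NULL, scale = c("hazard", "odds"),
                         conf_level = 0.95) {
  scale <- match.arg(scale)
  if (is.null(grid)) {
    grid <- seq(spec$knots[1L], spec$knots[length(spec$knots)], length.out = 101L)
  }
  idx <- fit$groups[[spec$variable]]
  if (is.null(idx)) {
    stop("fit contains no term group named '", spec$variable, "'")
  }
  beta <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  B <- rcs_basis(grid, spec)
  Bref <- rcs_basis(spec$x_ref, spec)
  C <- sweep(B, 2L, as.numeric(Bref))          # contrast rows
  logr <- drop(C %*% beta)
  se <- sqrt(pmax(rowSums((C %*% V) * C), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  extrap <- rep(FALSE, length(grid))
  if (!is.null(spec$x_range)) {
    extrap <- grid < spec$x_range[1L] | grid > spec$x_range[2L]
    if (any(extrap)) {
      warning("effect curve evaluated outside the training range for '",
              spec$variable, "' (flagged in column 'extrapolated')")
    }
  }
  out <- data.frame(x = grid, ratio = exp(logr),
                    lower = exp(logr - z * se), upper = exp(logr + z * se),
                    extrapolated = extrap)
  attr(out, "x_ref") <- spec$x_ref
  attr(out, "scale") <- scale
  class(out) <- c("effect_curve", "data.frame")
  out
}

#' Write an effect curve as delimited text
#'
#' @param curve an [effect_curve()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_effect_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
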