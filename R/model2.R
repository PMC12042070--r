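#' Model II regression: major axis and reduced major axis
#'
#' Observed-versus-predicted comparisons in this package treat both variables
#' as subject to error, so ordinary least squares is inappropriate; model II
#' regression is used instead. Two estimators are provided:
#'
#' * **Major axis (MA)**: the first principal axis of the sample covariance
#'   matrix; minimises perpendicular distances. Confidence limits follow
#'   Jolicoeur & Mosimann as tabulated in Sokal & Rohlf and implemented in
#'   the classical model II regression literature.
#' * **Reduced (standardised) major axis (RMA/SMA)**: slope
#'   \eqn{sign(r)\,s_y/s_x}; confidence limits from the correlation-based
#'   t interval.
#'
#' Both report the Pearson correlation and the variance explained by the
#' identity (1:1) line, \eqn{R^2_{1:1} = 1 - \sum(y-x)^2 / \sum(y-\bar y)^2},
#' which may be negative when the 1:1 line fits worse than the mean of `y`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite.
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `model2_fit`: list with `method`, `n`, `slope`,
#'   `intercept`, `slope_ci` (length-2), `intercept_ci`, `r` (correlation),
#'   `r2_identity`.
#' @name model2
NULL

.m2_check <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric", call. = FALSE)
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("x and y must be finite", call. = FALSE)
  if (length(x) < 3) stop("model II regression needs at least 3 points", call. = FALSE)
}

.m2_fit <- function(method, n, slope, intercept, slope_ci, intercept_ci, r, r2) {
  structure(list(method = method, n = n, slope = slope, intercept = intercept,
                 slope_ci = slope_ci, intercept_ci = intercept_ci,
                 r = r, r2_identity = r2),
            class = "model2_fit")
}

# intercept CI from the slope CI endpoints through the centroid
.intercept_ci <- function(slope_ci, xbar, ybar) {
  if (any(!is.finite(slope_ci))) return(c(-Inf, Inf))
  sort(ybar - slope_ci * xbar)
}

#' @rdname model2
#' @export
fit_major_axis <- function(x, y, alpha = 0.05) {
  .m2_check(x, y)
  n <- length(x)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) {
    stop("major axis slope is undefined when the covariance of x and y is zero",
         call. = FALSE)
  }
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * syy)
  # eigenvalues of the 2x2 covariance matrix, l1 >= l2
  tr <- sxx + syy
  disc <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (l2 <= 0) {
    # exactly collinear data: the axis is determined without error
    slope_ci <- c(slope, slope)
  } else {
    H <- stats::qf(1 - alpha, 1, n - 2) / ((l1 / l2 + l2 / l1 - 2) * (n - 2))
    if (H >= 1) {
      slope_ci <- c(-Inf, Inf)
    } else {
      A <- sqrt(H / (1 - H))
      dlo <- 1 + slope * A
      dhi <- 1 - slope * A
      if (dlo <= 0 || dhi <= 0) {
        # the confidence sector includes the vertical axis
        slope_ci <- c(-Inf, Inf)
      } else {
        slope_ci <- sort(c((slope - A) / dlo, (slope + A) / dhi))
      }
    }
  }
  .m2_fit("MA", n, slope, intercept, slope_ci,
          .intercept_ci(slope_ci, mean(x), mean(y)),
          r, r2_about_identity(x, y))
}

#' @rdname model2
#' @export
fit_rma <- function(x, y, alpha = 0.05) {
  .m2_check(x, y)
  n <- length(x)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0) stop("x has zero variance; RMA slope undefined", call. = FALSE)
  if (sy == 0) stop("y has zero variance; RMA slope undefined", call. = FALSE)
  r <- stats::cor(x, y)
  if (r == 0) stop("correlation is zero; RMA slope sign undefined", call. = FALSE)
  slope <- sign(r) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  B <- stats::qt(1 - alpha / 2, n - 2) * sqrt((1 - r^2) / (n - 2))
  slope_ci <- sort(slope * c(sqrt(B^2 + 1) - B, sqrt(B^2 + 1) + B))
  .m2_fit("RMA", n, slope, intercept, slope_ci,
          .intercept_ci(slope_ci, mean(x), mean(y)),
          r, r2_about_identity(x, y))
}

#' Variance explained by the 1:1 line
#'
#' \eqn{R^2_{1:1} = 1 - \sum(y - x)^2 / \sum(y - \bar y)^2}: how much of the
#' variance in `y` is accounted for by taking `x` at face value as its
#' prediction. Can be negative when the identity line fits worse than
#' \eqn{\bar y}.
#'
#' @param x Predicted values.
#' @param y Observed values.
#' @return Dimensionless; at most 1.
#' @export
r2_about_identity <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 points", call. = FALSE)
  ss_y <- sum((y - mean(y))^2)
  if (ss_y == 0) stop("y has zero variance; R^2 about the 1:1 line undefined", call. = FALSE)
  1 - sum((y - x)^2) / ss_y
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("<model2_fit> %s regression, n = %d\n", x$method, x$n))
  cat(sprintf("  slope:     %.4f  [%.4f, %.4f]\n", x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept: %.4f  [%.4f, %.4f]\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  r = %.4f, R^2 about 1:1 line = %.4f\n", x$r, x$r2_identity))
  invisible(x)
}

#' @export
as.data.frame.model2_fit <- function(x, ...) {
  data.frame(method = x$method, n = x$n,
             slope = x$slope, slope_lo = x$slope_ci[1], slope_hi = x$slope_ci[2],
             intercept = x$intercept, intercept_lo = x$intercept_ci[1],
             intercept_hi = x$intercept_ci[2],
             r = x$r, r2_identity = x$r2_identity)
}
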