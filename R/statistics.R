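# ---- double-angle vector statistics ------------------------------------

CHISQ2_95 <- 5.991465   # qchisq(0.95, df = 2); 95% region scaling constant

#' Centroid of a double-angle point cloud
#'
#' @param points matrix/data frame with 2 columns (C0, C45).
#' @return named numeric vector `(C0, C45)` of component-wise means.
#' @export
centroid <- function(points) {
  x <- .as_xy(points, "points")
  if (nrow(x) < 1) stop("need at least one point", call. = FALSE)
  colMeans(x)
}

#' 95% error ellipse of a bivariate astigmatism-vector distribution
#'
#' Assuming a bivariate normal distribution, the 95% confidence region is
#' the ellipse whose semi-axes are `sqrt(qchisq(0.95, 2) * lambda_i)` along
#' the eigenvectors of the sample covariance matrix (n-1 denominator); its
#' area is `pi * qchisq(0.95, 2) * sqrt(det(Sigma))`.
#'
#' @param points matrix/data frame with 2 columns (C0, C45); at least 3
#'   rows with non-degenerate covariance.
#' @param covariance optionally, a 2x2 covariance matrix to use directly
#'   (with `points` used only for the centroid, or omitted by passing a
#'   1-row `points` of centroid coordinates).
#' @return list of class `error_ellipse` with elements `centroid`,
#'   `covariance`, `semi_axes` (major, minor; dpt), `orientation` (degrees
#'   of the major axis, in `[0, 180)`), and `area` (dpt^2).
#' @examples
#' error_ellipse_95(cbind(rnorm(200), rnorm(200)))
#' @export
error_ellipse_95 <- function(points, covariance = NULL) {
  x <- .as_xy(points, "points")
  if (is.null(covariance)) {
    if (nrow(x) < 3)
      stop("need at least 3 points to estimate a covariance", call. = FALSE)
    covariance <- stats::cov(x)
  } else {
    covariance <- as.matrix(covariance)
    stopifnot(all(dim(covariance) == 2))
  }
  if (abs(covariance[1, 2] - covariance[2, 1]) > 1e-8 ||
      any(diag(covariance) < 0))
    stop("covariance must be symmetric positive semi-definite", call. = FALSE)
  dt <- det(covariance)
  if (dt <= .Machine$double.eps * max(1, sum(diag(covariance))^2))
    stop("degenerate ellipse: singular covariance", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE)
  semi <- sqrt(CHISQ2_95 * ev$values)             # major first
  orient <- normalize_axis(atan2(ev$vectors[2, 1], ev$vectors[1, 1]) / DEG)
  structure(list(centroid = centroid(x), covariance = covariance,
                 semi_axes = semi, orientation = orient,
                 area = pi * CHISQ2_95 * sqrt(dt)),
            class = "error_ellipse")
}

#' @export
print.error_ellipse <- function(x, ...) {
  cat(sprintf(
    "95%% error ellipse: centroid (%.4f, %.4f) dpt, area %.4f dpt^2\n",
    x$centroid[1], x$centroid[2], x$area))
  cat(sprintf("  semi-axes %.4f / %.4f dpt at %.1f deg\n",
              x$semi_axes[1], x$semi_axes[2], x$orientation))
  invisible(x)
}

#' Polygon vertices of an error ellipse
#'
#' For plotting or export: points on the ellipse boundary in double-angle
#' coordinates.
#'
#' @param ellipse an [error_ellipse_95()] object.
#' @param n number of vertices.
#' @return data frame with columns `C0`, `C45`.
#' @export
ellipse_points <- function(ellipse, n = 181) {
  stopifnot(inherits(ellipse, "error_ellipse"))
  th <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  phi <- ellipse$orientation * DEG
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  xy <- cbind(a * cos(th), b * sin(th)) %*% t(rot)
  data.frame(C0 = xy[, 1] + ellipse$centroid[1],
             C45 = xy[, 2] + ellipse$centroid[2])
}

.check_pairs <- function(pred, actual) {
  p <- .as_xy(pred, "pred"); a <- .as_xy(actual, "actual")
  if (nrow(p) != nrow(a) || nrow(p) < 1)
    stop("pred and actual must have the same, positive number of rows",
         call. = FALSE)
  list(p = p, a = a)
}

#' Mean vector difference (MVD)
#'
#' Mean over eyes of the length of the 2-D prediction-error vector, in
#' dioptres.
#'
#' @param pred,actual matrices/data frames with 2 columns (C0, C45).
#' @return MVD in dpt.
#' @export
mean_vector_difference <- function(pred, actual) {
  z <- .check_pairs(pred, actual)
  mean(sqrt(rowSums((z$a - z$p)^2)))
}

#' Mean squared prediction error (MSE)
#'
#' Mean over eyes of the squared length of the 2-D prediction-error vector,
#' in dpt^2.  Always >= MVD^2 (Jensen), with equality iff all error vectors
#' have the same length.
#'
#' @inheritParams mean_vector_difference
#' @return MSE in dpt^2.
#' @export
mean_squared_error <- function(pred, actual) {
  z <- .check_pairs(pred, actual)
  mean(rowSums((z$a - z$p)^2))
}

#' Descriptive summary of a numeric series
#'
#' Arithmetic mean, standard deviation (n-1), median, and the 2.5% / 97.5%
#' quantiles bounding the empirical 95% interval.
#'
#' @param values numeric vector, length >= 2.
#' @param quantile_type interpolation rule passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return one-row data frame: `mean`, `sd`, `median`, `q2.5`, `q97.5`.
#' @export
descriptive_summary <- function(values, quantile_type = 7) {
  stopifnot(is.numeric(values), length(values) >= 2, all(is.finite(values)))
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), type = quantile_type,
                       names = FALSE)
  data.frame(mean = mean(values), sd = stats::sd(values), median = q[2],
             q2.5 = q[1], q97.5 = q[3])
}

#' Evaluate a prediction model on one data split
#'
#' Computes prediction errors `actual - predicted` and reports the
#' double-angle summary used throughout: centroid coordinates, 95%
#' error-ellipse area, MVD and MSE.
#'
#' @param model fitted `astig_model` (or `NULL` to evaluate the raw
#'   differences `actual - x`).
#' @param x measured astigmatism vectors (2 columns, C0/C45).
#' @param actual reconstructed-cornea astigmatism vectors.
#' @return one-row data frame: `centroid_C0`, `centroid_C45`,
#'   `ellipse_area`, `MVD`, `MSE`, `n`.
#' @export
evaluate_predictions <- function(model, x, actual) {
  x <- .as_xy(x); actual <- .as_xy(actual, "actual")
  pred <- if (is.null(model)) x else predict(model, x)
  err <- actual - pred
  # a degenerate error cloud (e.g. a perfect predictor) has zero area
  area <- tryCatch(error_ellipse_95(err)$area, error = function(e) 0)
  data.frame(
    centroid_C0 = mean(err[, 1]),
    centroid_C45 = mean(err[, 2]),
    ellipse_area = area,
    MVD = mean_vector_difference(pred, actual),
    MSE = mean_squared_error(pred, actual),
    n = nrow(x)
  )
}
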