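# ---- prediction models: measured astigmatism vector -> recCP vector ----
#
# All three model families map a 2-vector (C0, C45) of measured corneal
# astigmatism to the corresponding components of the reconstructed corneal
# power.  Fitting functions return S3 objects inheriting "astig_model".

.as_xy <- function(x, what = "x") {
  x <- as.matrix(x)
  if (ncol(x) != 2)
    stop(what, " must have exactly 2 columns (C0, C45)", call. = FALSE)
  if (!all(is.finite(x)))
    stop("non-finite values in ", what, call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- c("C0", "C45")
  x
}

#' Fit an astigmatism prediction model
#'
#' Front door dispatching to [fit_constant_model()],
#' [fit_bivariate_regression()] or [fit_shallow_net()].
#'
#' @param x measured astigmatism vectors: matrix/data frame with 2 columns
#'   (C0, C45), dioptres, right-eye frame.
#' @param y target reconstructed-cornea astigmatism vectors, same shape.
#' @param method one of `"regression"`, `"constant"`, `"net"`.
#' @param ... passed to the specific fitting function (for `"net"`:
#'   `x_val`, `y_val`, `control`).
#' @return an object inheriting `astig_model`.
#' @export
astig_model <- function(x, y, method = c("regression", "constant", "net"),
                        ...) {
  method <- match.arg(method)
  switch(method,
         regression = fit_bivariate_regression(x, y, ...),
         constant   = fit_constant_model(x, y, ...),
         net        = fit_shallow_net(x, y, ...))
}

# shared constructor bookkeeping
.finish_model <- function(object, x, y) {
  object$fitted <- predict(object, x)
  object$residuals <- y - object$fitted
  object$n <- nrow(x)
  object
}

#' Constant centroid-correction model
#'
#' Adds a fixed offset to the measured vector: `offset = mean(y) - mean(x)`.
#' On its own training data the corrected centroid error is exactly zero,
#' and the error-ellipse area of the residuals is unchanged relative to the
#' raw differences (the whole cloud is only shifted).
#'
#' @inheritParams astig_model
#' @return object of class `c("astig_constant", "astig_model")`.
#' @export
fit_constant_model <- function(x, y) {
  x <- .as_xy(x); y <- .as_xy(y, "y")
  if (nrow(x) != nrow(y) || nrow(x) < 1)
    stop("x and y must have the same, positive number of rows", call. = FALSE)
  obj <- structure(list(offset = colMeans(y) - colMeans(x),
                        call = match.call()),
                   class = c("astig_constant", "astig_model"))
  .finish_model(obj, x, y)
}

#' Bivariate linear regression model
#'
#' Ordinary least squares with intercept, fitted per output component; for
#' complete data this is the fixed point of the ECM maximum-likelihood
#' iteration for a bivariate-normal residual model, so the estimates are the
#' ML estimates.  The log-likelihood is reported at the ML (divide-by-N)
#' residual covariance.
#'
#' @inheritParams astig_model
#' @return object of class `c("astig_reg", "astig_model")` with elements
#'   `A` (2x2 coefficient matrix), `b` (intercept 2-vector), `logL`, and the
#'   ML residual covariance `sigma`.
#' @export
fit_bivariate_regression <- function(x, y) {
  x <- .as_xy(x); y <- .as_xy(y, "y")
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y row counts differ", call. = FALSE)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  X <- cbind(1, x)
  qx <- qr(X)
  if (qx$rank < 3)
    stop("singular design: measured astigmatism vectors are collinear",
         call. = FALSE)
  B <- qr.coef(qx, y)                       # 3 x 2: intercept row + slopes
  A <- t(B[2:3, , drop = FALSE])            # prediction = A %*% x + b
  b <- B[1, ]
  E <- y - X %*% B
  sigma <- crossprod(E) / n
  logL <- -n / 2 * (2 * log(2 * pi) + determinant(sigma)$modulus[1] + 2)
  obj <- structure(list(A = A, b = b, logL = as.numeric(logL), sigma = sigma,
                        call = match.call()),
                   class = c("astig_reg", "astig_model"))
  .finish_model(obj, x, y)
}

#' Published bivariate regression models
#'
#' The five fixed regression models mapping measured astigmatism vector
#' components to reconstructed corneal power, one per measurement modality:
#' IOLMaster 700 keratometry (IOLMK), Galilei G4 keratometry (GK), total
#' corneal power (TCP2), and the area-integrated front-surface (CorT) and
#' total (CorTTP) corneal powers.
#'
#' @return named list of `astig_reg` objects (coefficients only, no
#'   training data).
#' @examples
#' predict(published_models()$IOLMK, cbind(0, 0))   # the intercept
#' @export
published_models <- function() {
  tab <- list(
    IOLMK  = list(A = c(0.543,  0.070, -0.010, 0.375), b = c(-0.304, -0.043),
                  logL = -332),
    GK     = list(A = c(0.524,  0.010, -0.024, 0.336), b = c(-0.392, -0.023),
                  logL = -337),
    TCP2   = list(A = c(0.508, -0.051, -0.002, 0.269), b = c(-0.252, -0.021),
                  logL = -277),
    CorT   = list(A = c(0.559, -0.088,  0.038, 0.314), b = c(-0.302, -0.053),
                  logL = -276),
    CorTTP = list(A = c(0.512, -0.006,  0.022, 0.313), b = c(-0.236, -0.024),
                  logL = -257)
  )
  lapply(tab, function(m) {
    A <- matrix(m$A, 2, 2, byrow = TRUE,
                dimnames = list(c("C0", "C45"), c("C0", "C45")))
    b <- stats::setNames(m$b, c("C0", "C45"))
    structure(list(A = A, b = b, logL = m$logL, sigma = NULL, call = NULL),
              class = c("astig_reg", "astig_model"))
  })
}

# ---- S3 methods --------------------------------------------------------

#' Predict method for astigmatism models
#'
#' @param object a fitted `astig_model`.
#' @param newdata matrix/data frame with 2 columns (C0, C45).
#' @param ... unused.
#' @return matrix with columns `C0`, `C45`.
#' @export
predict.astig_constant <- function(object, newdata, ...) {
  x <- .as_xy(newdata)
  sweep(x, 2, object$offset, `+`)
}

#' @rdname predict.astig_constant
#' @export
predict.astig_reg <- function(object, newdata, ...) {
  x <- .as_xy(newdata)
  out <- x %*% t(object$A)
  out <- sweep(out, 2, object$b, `+`)
  colnames(out) <- c("C0", "C45")
  out
}

#' @export
coef.astig_constant <- function(object, ...) object$offset

#' @export
coef.astig_reg <- function(object, ...) {
  cbind(intercept = object$b, object$A)
}

#' @export
residuals.astig_model <- function(object, ...) object$residuals

#' @export
fitted.astig_model <- function(object, ...) object$fitted

#' @export
print.astig_constant <- function(x, ...) {
  cat("Constant centroid-correction model\n")
  cat(sprintf("  offset (C0, C45): %.4f, %.4f dpt\n",
              x$offset[1], x$offset[2]))
  invisible(x)
}

#' @export
print.astig_reg <- function(x, ...) {
  cat("Bivariate linear astigmatism model: pred = A x + b\n")
  cat("  A =\n")
  print(round(x$A, 4))
  cat(sprintf("  b = (%.4f, %.4f) dpt", x$b[1], x$b[2]))
  if (!is.null(x$logL)) cat(sprintf(",  logL = %.1f", x$logL))
  cat("\n")
  invisible(x)
}

#' Summary of a fitted astigmatism model
#'
#' Reports the double-angle residual statistics on the training data:
#' centroid, 95% error-ellipse area, mean vector difference and mean squared
#' prediction error.
#'
#' @param object a fitted `astig_model` with stored residuals.
#' @param ... unused.
#' @return data frame of residual statistics (invisible for print).
#' @export
summary.astig_model <- function(object, ...) {
  if (is.null(object$residuals))
    stop("model carries no training residuals", call. = FALSE)
  r <- object$residuals
  zero <- matrix(0, nrow(r), 2)
  out <- data.frame(
    n = nrow(r),
    centroid_C0 = mean(r[, 1]),
    centroid_C45 = mean(r[, 2]),
    ellipse_area = error_ellipse_95(r)$area,
    MVD = mean_vector_difference(zero, r),
    MSE = mean_squared_error(zero, r)
  )
  class(out) <- c("summary.astig_model", "data.frame")
  out
}

#' Double-angle residual plot for a fitted astigmatism model
#'
#' Plots the training residual cloud in double-angle coordinates with its
#' centroid and 95% error ellipse.
#'
#' @param x fitted `astig_model` with residuals.
#' @param ... passed to [plot.default()].
#' @return invisibly, the residual [error_ellipse_95()] object.
#' @export
plot.astig_model <- function(x, ...) {
  r <- x$residuals
  if (is.null(r)) stop("model carries no training residuals", call. = FALSE)
  ell <- error_ellipse_95(r)
  poly <- ellipse_points(ell)
  lim <- range(r, poly)
  plot(r[, 1], r[, 2], xlab = "C0 (dpt)", ylab = "C45 (dpt)",
       xlim = lim, ylim = lim, asp = 1, ...)
  graphics::lines(poly$C0, poly$C45, lty = 2)
  graphics::points(ell$centroid[1], ell$centroid[2], pch = 19)
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(ell)
}
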