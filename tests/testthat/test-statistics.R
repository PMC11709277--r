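# double-angle vector statistics

test_that("centroid is the component-wise mean", {
  expect_equal(centroid(matrix(c(1, 1), 1)), c(C0 = 1, C45 = 1))
  expect_equal(centroid(rbind(c(1, 0), c(-1, 0))), c(C0 = 0, C45 = 0))
  set.seed(1)
  n <- 4000
  pts <- cbind(rnorm(n, 0.0046, 0.8585), rnorm(n, -0.0598, 0.5341))
  cen <- centroid(pts)
  expect_lt(abs(cen[1] - 0.0046), 3 * 0.8585 / sqrt(n))
  expect_lt(abs(cen[2] + 0.0598), 3 * 0.5341 / sqrt(n))
  expect_error(centroid(pts[0, ]), "at least one")
})

test_that("95% ellipse closed forms", {
  dummy <- rbind(c(0, 0), c(1, 0), c(0, 1))
  iso <- error_ellipse_95(dummy, covariance = diag(2))
  expect_close(iso$area, pi * 5.991465, tol = 1e-6)
  expect_close(iso$semi_axes, rep(sqrt(5.991465), 2), tol = 1e-9)
  # printed-SD check under zero correlation
  ell <- error_ellipse_95(dummy, covariance = diag(c(0.8734^2, 0.5118^2)))
  expect_lt(abs(ell$area - 8.4136) / 8.4136, 0.001)
  expect_error(error_ellipse_95(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("ellipse Monte Carlo coverage is 95%", {
  set.seed(2)
  n <- 1e5
  S <- matrix(c(0.45, 0.1, 0.1, 0.2), 2)
  L <- chol(S)
  pts <- matrix(rnorm(2 * n), n, 2) %*% L
  pts <- sweep(pts, 2, c(-0.31, -0.05), `+`)
  ell <- error_ellipse_95(pts)
  d2 <- mahalanobis(pts, ell$centroid, ell$covariance)
  expect_lt(abs(mean(d2 <= 5.991465) - 0.95), 0.003)
  # the polygon encloses the same region: vertices sit on the boundary
  poly <- ellipse_points(ell)
  expect_close(mahalanobis(as.matrix(poly), ell$centroid, ell$covariance),
               rep(5.991465, nrow(poly)), tol = 1e-6)
})

test_that("ellipse area is rotation-invariant and scales quadratically", {
  set.seed(3)
  pts <- cbind(rnorm(400, 0, 0.9), rnorm(400, 0, 0.4))
  a0 <- error_ellipse_95(pts)$area
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_close(error_ellipse_95(pts %*% rot)$area, a0, tol = 1e-9)
  expect_close(error_ellipse_95(pts * 2.5)$area, a0 * 2.5^2, tol = 1e-8)
})

test_that("MVD and MSE definitions and Jensen inequality", {
  p <- rbind(c(0, 0)); a <- rbind(c(3, 4))
  expect_equal(mean_vector_difference(p, p), 0)
  expect_equal(mean_vector_difference(p, a), 5)
  expect_equal(mean_squared_error(p, a), 25)
  p2 <- rbind(c(0, 0), c(0, 0)); a2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(mean_vector_difference(p2, a2), 1)
  set.seed(4)
  pr <- cbind(rnorm(300), rnorm(300)); ac <- cbind(rnorm(300), rnorm(300))
  mvd <- mean_vector_difference(pr, ac)
  mse <- mean_squared_error(pr, ac)
  expect_gte(mse, mvd^2)
  # equality when all error vectors share one length
  th <- runif(50, 0, 2 * pi)
  ac3 <- 2 * cbind(cos(th), sin(th))
  expect_close(mean_squared_error(ac3 * 0, ac3),
               mean_vector_difference(ac3 * 0, ac3)^2, tol = 1e-10)
  expect_error(mean_squared_error(pr, ac[1:10, ]), "same")
})

test_that("MSE converges to trace(Sigma) + |mu|^2", {
  set.seed(5)
  n <- 2e5
  mu <- c(-0.3, 0.05); sds <- c(0.6, 0.4)
  d <- cbind(rnorm(n, mu[1], sds[1]), rnorm(n, mu[2], sds[2]))
  expect_lt(abs(mean_squared_error(d * 0, d) -
                  (sum(sds^2) + sum(mu^2))), 0.01)
})

test_that("descriptive summary matches known distributions", {
  cst <- descriptive_summary(rep(2.5, 10))
  expect_equal(cst$sd, 0)
  expect_true(all(unlist(cst[c("mean", "median", "q2.5", "q97.5")]) == 2.5))
  expect_equal(descriptive_summary(1:100)$median, 50.5)
  set.seed(6)
  z <- rnorm(1e5)
  expect_lt(abs(descriptive_summary(z)$q97.5 - 1.96), 0.02)
})

test_that("evaluate_predictions reports the double-angle summary", {
  set.seed(7)
  x <- cbind(rnorm(200, 0, 0.8), rnorm(200, 0, 0.5))
  y <- x %*% matrix(c(0.5, 0, 0, 0.4), 2) + rep(c(-0.3, -0.04), each = 200) +
    matrix(rnorm(400, 0, 0.3), 200)
  con <- fit_constant_model(x, y)
  row <- evaluate_predictions(con, x, y)
  expect_close(c(row$centroid_C0, row$centroid_C45), c(0, 0), tol = 1e-12)
  raw <- evaluate_predictions(NULL, x, y)
  expect_close(row$ellipse_area, raw$ellipse_area, tol = 1e-10)
  reg <- fit_bivariate_regression(x, y)
  rrow <- evaluate_predictions(reg, x, y)
  expect_close(c(rrow$centroid_C0, rrow$centroid_C45), c(0, 0), tol = 1e-10)
  # perfect predictor: all metrics zero
  perfect <- evaluate_predictions(NULL, y, y)
  expect_equal(unlist(perfect[1, 1:5]), c(centroid_C0 = 0, centroid_C45 = 0,
                                          ellipse_area = 0, MVD = 0, MSE = 0))
})
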