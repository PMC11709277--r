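# constant, bivariate regression, and published models

test_that("constant model is the centroid shift", {
  x <- matrix(c(0.0046, -0.0598), 1, 2)
  y <- matrix(c(-0.3149, -0.0498), 1, 2)
  m <- fit_constant_model(x, y)
  expect_close(m$offset, c(-0.3195, 0.0100), tol = 1e-10)
  expect_equal(round(m$offset, 2), c(C0 = -0.32, C45 = 0.01))

  set.seed(2)
  x <- cbind(rnorm(100), rnorm(100)); y <- cbind(rnorm(100), rnorm(100))
  m <- fit_constant_model(x, y)
  # corrected training centroid at the origin
  expect_close(colMeans(residuals(m)), c(0, 0), tol = 1e-12)
  # the shift leaves the error-ellipse area unchanged
  raw_area <- error_ellipse_95(y - x)$area
  expect_close(error_ellipse_95(residuals(m))$area, raw_area, tol = 1e-10)
  expect_close(coef(fit_constant_model(x, x)), c(0, 0), tol = 1e-15)
})

test_that("bivariate regression equals the multivariate lm oracle", {
  set.seed(8)
  x <- cbind(rnorm(150, 0, 0.8), rnorm(150, 0, 0.5))
  y <- cbind(-0.3 + 0.5 * x[, 1] + rnorm(150, 0, 0.3),
             0.05 + 0.4 * x[, 2] + rnorm(150, 0, 0.3))
  m <- fit_bivariate_regression(x, y)
  orc <- lm(y ~ x)
  expect_close(m$b, coef(orc)[1, ], tol = 1e-8)
  expect_close(m$A, t(coef(orc)[2:3, ]), tol = 1e-8)
  # ML log-likelihood oracle: per-point bivariate normal density at the
  # ML residual covariance, summed
  E <- residuals(orc)
  S <- crossprod(E) / nrow(E)
  logL_orc <- sum(-log(2 * pi) - 0.5 * log(det(S)) -
                    0.5 * mahalanobis(E, c(0, 0), S))
  expect_close(m$logL, logL_orc, tol = 1e-6)
  # residual centroid at the origin
  expect_close(colMeans(residuals(m)), c(0, 0), tol = 1e-10)
  # exact fit edge case
  mid <- fit_bivariate_regression(x, x)
  expect_close(mid$A, diag(2), tol = 1e-10)
  expect_close(mid$b, c(0, 0), tol = 1e-10)
})

test_that("regression recovers known coefficients within 3 SE", {
  set.seed(13)
  n <- 2000
  A0 <- matrix(c(0.54, 0.07, -0.01, 0.38), 2, 2, byrow = TRUE)
  b0 <- c(-0.30, -0.04)
  x <- cbind(rnorm(n, 0, 0.86), rnorm(n, 0, 0.53))
  y <- x %*% t(A0) + rep(b0, each = n) + matrix(rnorm(2 * n, 0, 0.3), n, 2)
  m <- fit_bivariate_regression(x, y)
  # analytic OLS standard errors per output component
  X <- cbind(1, x)
  xtxi <- solve(crossprod(X))
  for (j in 1:2) {
    s2 <- sum((y[, j] - X %*% c(b0[j], A0[j, ]))^2) / (n - 3)
    se <- sqrt(diag(xtxi) * s2)
    est <- c(m$b[j], m$A[j, ])
    expect_true(all(abs(est - c(b0[j], A0[j, ])) < 3 * se))
  }
})

test_that("collinear designs are rejected", {
  x <- cbind(1:10, 2 * (1:10))
  y <- cbind(rnorm(10), rnorm(10))
  expect_error(fit_bivariate_regression(x, y), "collinear")
  expect_error(fit_bivariate_regression(x[1:2, ], y[1:2, ]), "at least 3")
})

test_that("published models carry the fixed coefficients", {
  pub <- published_models()
  expect_named(pub, c("IOLMK", "GK", "TCP2", "CorT", "CorTTP"))
  expect_close(predict(pub$IOLMK, cbind(0, 0)), c(-0.304, -0.043),
               tol = 1e-12)
  expect_close(predict(pub$IOLMK, cbind(1, 0)) - predict(pub$IOLMK,
                                                         cbind(0, 0)),
               c(0.543, -0.010), tol = 1e-12)
  expect_equal(pub$CorTTP$b, c(C0 = -0.236, C45 = -0.024))
  expect_equal(pub$IOLMK$A["C0", "C0"], 0.543)
  # all diagonal entries shrink large measured astigmatism
  for (m in pub) expect_true(all(diag(m$A) < 1))
})

test_that("linear predictions are affine and identity model passes through", {
  xx <- cbind(rnorm(20), rnorm(20))
  id <- fit_bivariate_regression(xx, xx)
  z <- cbind(runif(7, -2, 2), runif(7, -2, 2))
  expect_close(predict(id, z), z, tol = 1e-8)
  m <- published_models()$GK
  expect_close(predict(m, z), z %*% t(m$A) + rep(m$b, each = 7), tol = 1e-12)
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(4)
  x <- cbind(rnorm(60, 0, 0.8), rnorm(60, 0, 0.5))
  y <- x %*% matrix(c(0.5, 0, 0, 0.4), 2) + matrix(rnorm(120, 0, 0.2), 60)
  z <- cbind(runif(9, -2, 2), runif(9, -2, 2))
  reg <- fit_bivariate_regression(x, y)
  con <- fit_constant_model(x, y)
  net <- fit_shallow_net(x[1:40, ], y[1:40, ], x[41:60, ], y[41:60, ],
                         control = net_control(max_epochs = 50, seed = 2))
  for (m in list(reg, con, net)) {
    f <- withr::local_tempfile(fileext = ".json")
    write_astig_model(m, f)
    m2 <- read_astig_model(f)
    expect_close(predict(m2, z), predict(m, z), tol = 1e-12)
  }
})
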