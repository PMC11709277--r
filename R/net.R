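# ---- shallow feedforward network (2 -> 12 -> 12 -> 2) ------------------
#
# Hand-rolled fully connected regressor with two tanh hidden layers and a
# linear output layer, trained by full-batch Adam on the mean squared
# 2-D error with early stopping on a validation split.  Inputs and outputs
# are rescaled to [-1, 1] by the training range (the usual shallow-fitnet
# preprocessing), which keeps the tanh units in their active region.

#' Training control for the shallow network
#'
#' @param hidden sizes of the two hidden layers.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of full-batch epochs.
#' @param check_every validation-MSE check interval in epochs.
#' @param patience number of consecutive validation checks without
#'   improvement before stopping; the best-so-far weights are kept.
#' @param seed integer seed for the weight initialisation.
#' @return list of class `net_control`.
#' @export
net_control <- function(hidden = c(12, 12), learning_rate = 0.02,
                        max_epochs = 1000, check_every = 10, patience = 6,
                        seed = 1) {
  stopifnot(length(hidden) == 2, all(hidden >= 1), learning_rate > 0,
            max_epochs >= 0, check_every >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 check_every = as.integer(check_every),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "net_control")
}

# range scaling to [-1, 1]; degenerate (constant) columns map to 0
.fit_scaler <- function(m) {
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}
.scale_to <- function(m, s) sweep(sweep(m, 2, s$lo), 2, s$span, `/`) * 2 - 1
.scale_from <- function(m, s) sweep(sweep((m + 1) / 2, 2, s$span, `*`), 2,
                                    s$lo, `+`)

.net_forward <- function(w, X) {
  H1 <- tanh(X %*% w$W1 + rep(w$b1, each = nrow(X)))
  H2 <- tanh(H1 %*% w$W2 + rep(w$b2, each = nrow(H1)))
  list(H1 = H1, H2 = H2,
       out = H2 %*% w$W3 + rep(w$b3, each = nrow(H2)))
}

# mean squared 2-D error-vector length
.mse2 <- function(pred, y) mean(rowSums((pred - y)^2))

#' Fit the shallow feedforward astigmatism network
#'
#' Trains a 2 -> 12 -> 12 -> 2 network (tanh hidden layers, linear output)
#' mapping measured astigmatism vectors to reconstructed-cornea vectors.
#' The training set drives the weight updates; the validation set is
#' monitored for early stopping and the weights achieving the lowest
#' validation MSE are returned.  Fully deterministic given
#' `control$seed` (the global RNG state is restored on exit).
#'
#' @inheritParams astig_model
#' @param x_val,y_val validation split (same shapes as `x`, `y`).
#' @param control a [net_control()] list.
#' @return object of class `c("astig_net", "astig_model")` with the layer
#'   weights, range scalers, seed, epochs run, and final training and
#'   validation MSE (dpt^2, original scale).
#' @export
fit_shallow_net <- function(x, y, x_val, y_val, control = net_control()) {
  x <- .as_xy(x); y <- .as_xy(y, "y")
  x_val <- .as_xy(x_val, "x_val"); y_val <- .as_xy(y_val, "y_val")
  if (nrow(x) != nrow(y) || nrow(x_val) != nrow(y_val))
    stop("x/y row counts differ", call. = FALSE)
  if (nrow(x) < 1 || nrow(x_val) < 1)
    stop("training and validation sets must be non-empty", call. = FALSE)

  sx <- .fit_scaler(x); sy <- .fit_scaler(y)
  Xs <- .scale_to(x, sx); Ys <- .scale_to(y, sy)
  Xv <- .scale_to(x_val, sx); Yv <- .scale_to(y_val, sy)

  h <- control$hidden
  sizes <- list(W1 = c(2, h[1]), b1 = c(1, h[1]),
                W2 = c(h[1], h[2]), b2 = c(1, h[2]),
                W3 = c(h[2], 2), b3 = c(1, 2))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(control$seed)
  w <- lapply(sizes, function(d) {
    s <- sqrt(6 / (d[1] + d[2]))                  # Glorot-uniform fan scaling
    matrix(stats::runif(prod(d), -s, s), d[1], d[2])
  })
  w$b1[] <- 0; w$b2[] <- 0; w$b3[] <- 0

  mom <- lapply(w, function(m) m * 0)             # Adam first moment
  vel <- lapply(w, function(m) m * 0)             # Adam second moment
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- control$learning_rate
  n <- nrow(Xs)

  best <- list(w = w, val = .mse2(.net_forward(w, Xv)$out, Yv), epoch = 0L)
  fails <- 0L
  epoch <- 0L
  converged <- TRUE
  while (epoch < control$max_epochs) {
    epoch <- epoch + 1L
    fw <- .net_forward(w, Xs)
    d_out <- 2 * (fw$out - Ys) / n                # d(mean rowSums sq)/d out
    g <- list()
    g$W3 <- crossprod(fw$H2, d_out); g$b3 <- matrix(colSums(d_out), 1)
    d2 <- (d_out %*% t(w$W3)) * (1 - fw$H2^2)
    g$W2 <- crossprod(fw$H1, d2); g$b2 <- matrix(colSums(d2), 1)
    d1 <- (d2 %*% t(w$W2)) * (1 - fw$H1^2)
    g$W1 <- crossprod(Xs, d1); g$b1 <- matrix(colSums(d1), 1)
    for (k in names(w)) {
      mom[[k]] <- beta1 * mom[[k]] + (1 - beta1) * g[[k]]
      vel[[k]] <- beta2 * vel[[k]] + (1 - beta2) * g[[k]]^2
      mhat <- mom[[k]] / (1 - beta1^epoch)
      vhat <- vel[[k]] / (1 - beta2^epoch)
      w[[k]] <- w[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (epoch %% control$check_every == 0) {
      val <- .mse2(.net_forward(w, Xv)$out, Yv)
      if (val < best$val - 1e-12) {
        best <- list(w = w, val = val, epoch = epoch)
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= control$patience) break
      }
    }
  }
  if (epoch == control$max_epochs && fails < control$patience &&
      control$max_epochs > 0)
    converged <- FALSE                            # stopped by epoch budget

  w <- best$w
  obj <- structure(list(weights = w, scaler_x = sx, scaler_y = sy,
                        control = control, seed = control$seed,
                        epochs_run = epoch, best_epoch = best$epoch,
                        converged = converged,
                        call = match.call()),
                   class = c("astig_net", "astig_model"))
  obj <- .finish_model(obj, x, y)
  obj$train_mse <- .mse2(obj$fitted, y)
  obj$val_mse <- .mse2(predict(obj, x_val), y_val)
  obj
}

#' @rdname predict.astig_constant
#' @export
predict.astig_net <- function(object, newdata, ...) {
  x <- .as_xy(newdata)
  out <- .scale_from(.net_forward(object$weights,
                                  .scale_to(x, object$scaler_x))$out,
                     object$scaler_y)
  colnames(out) <- c("C0", "C45")
  out
}

#' @export
coef.astig_net <- function(object, ...) object$weights

#' @export
print.astig_net <- function(x, ...) {
  h <- x$control$hidden
  cat(sprintf("Shallow feedforward astigmatism network 2-%d-%d-2 (tanh)\n",
              h[1], h[2]))
  cat(sprintf("  seed %d, stopped after %d epochs (best at %d)\n",
              x$seed, x$epochs_run, x$best_epoch))
  if (!is.null(x$train_mse))
    cat(sprintf("  training MSE %.4f, validation MSE %.4f dpt^2\n",
                x$train_mse, x$val_mse))
  if (!isTRUE(x$converged))
    cat("  note: epoch budget reached before validation stopping\n")
  invisible(x)
}
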