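# ---- model serialization (JSON) ----------------------------------------

#' Write a fitted astigmatism model to JSON
#'
#' Serialises the parameters needed to reproduce predictions (coefficient
#' matrices, network weights and range scalers, seed) plus light training
#' metadata.  Training residuals are not stored.
#'
#' @param object a fitted `astig_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_astig_model <- function(object, path) {
  stopifnot(inherits(object, "astig_model"))
  payload <- if (inherits(object, "astig_reg")) {
    list(type = "regression", A = object$A, b = object$b, logL = object$logL)
  } else if (inherits(object, "astig_constant")) {
    list(type = "constant", offset = object$offset)
  } else if (inherits(object, "astig_net")) {
    list(type = "net",
         weights = lapply(object$weights, unclass),
         scaler_x = object$scaler_x, scaler_y = object$scaler_y,
         hidden = object$control$hidden, seed = object$seed,
         epochs_run = object$epochs_run, best_epoch = object$best_epoch,
         train_mse = object$train_mse, val_mse = object$val_mse)
  } else stop("unknown model class", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted astigmatism model from JSON
#'
#' @param path file written by [write_astig_model()].
#' @return the reconstructed `astig_model` (prediction-equivalent to the
#'   original; training residuals are not restored).
#' @export
read_astig_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm2 <- c("C0", "C45")
  if (p$type == "regression") {
    structure(list(A = matrix(as.numeric(t(p$A)), 2, 2, byrow = TRUE,
                              dimnames = list(nm2, nm2)),
                   b = stats::setNames(as.numeric(p$b), nm2),
                   logL = p$logL, sigma = NULL, call = NULL),
              class = c("astig_reg", "astig_model"))
  } else if (p$type == "constant") {
    structure(list(offset = stats::setNames(as.numeric(p$offset), nm2),
                   call = NULL),
              class = c("astig_constant", "astig_model"))
  } else if (p$type == "net") {
    w <- lapply(p$weights, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "double"; dimnames(m) <- NULL; m
    })
    # biases serialise as 1-row matrices; vectors come back as 1-col
    for (k in c("b1", "b2", "b3"))
      w[[k]] <- matrix(as.numeric(w[[k]]), nrow = 1)
    ctl <- net_control(hidden = as.integer(p$hidden), seed = p$seed)
    structure(list(weights = w,
                   scaler_x = lapply(p$scaler_x, as.numeric),
                   scaler_y = lapply(p$scaler_y, as.numeric),
                   control = ctl, seed = p$seed,
                   epochs_run = p$epochs_run, best_epoch = p$best_epoch,
                   train_mse = p$train_mse, val_mse = p$val_mse,
                   converged = TRUE, call = NULL),
              class = c("astig_net", "astig_model"))
  } else stop("unknown model type in file: ", p$type, call. = FALSE)
}
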