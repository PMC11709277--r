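# ---- end-to-end pipeline -----------------------------------------------

#' Split a dataset into training / validation / test index sets
#'
#' Uniform random permutation with sizes `round(0.6 n)`, `round(0.2 n)` and
#' the remainder (305 / 102 / 102 for n = 509).  Deterministic given the
#' seed; the global RNG state is restored on exit.
#'
#' @param n number of records (>= 5).
#' @param seed integer seed.
#' @param fractions training and validation fractions (the test set takes
#'   the remainder).
#' @return list of class `split_spec` with integer index vectors `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(n, seed = 1, fractions = c(0.6, 0.2)) {
  stopifnot(n >= 5, length(fractions) == 2, all(fractions > 0),
            sum(fractions) < 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  structure(list(train = sort(perm[seq_len(n_train)]),
                 validation = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[(n_train + n_val + 1):n]),
                 seed = seed),
            class = "split_spec")
}

.derive_seed <- function(seed, k) as.integer((seed * 7919 + k) %% 2147483629)

#' Run the full astigmatism-mapping analysis
#'
#' Orchestrates the pipeline: read or simulate a cohort; decompose all
#' readings into power vectors and mirror left eyes; reconstruct the
#' corneal power vector per eye; split 60/20/20; fit the requested model
#' families per modality on the training split (the network also uses the
#' validation split); evaluate raw differences and model prediction errors
#' on training and test; and write the report (CSV + JSON), serialized
#' models, double-angle plot data, and a run log.  All randomness derives
#' deterministically from `seed`.
#'
#' @param output_dir directory for the artifacts (created if needed).
#' @param seed master seed; sub-seeds for simulation, splitting and network
#'   initialisation are derived from it.
#' @param input_csv optional cohort CSV ([read_cohort_csv()] schema); when
#'   `NULL` a cohort is simulated from `cohort`.
#' @param cohort [cohort_config()] used when simulating (its seed is
#'   overridden by the derived sub-seed).
#' @param modalities modalities to evaluate.
#' @param model_families subset of `c("constant", "regression", "net")`.
#' @param control [net_control()] for the network (seed overridden).
#' @param hc,ec model constants.
#' @return invisibly, the report data frame (one row per modality x model x
#'   split, including the raw `none` rows).
#' @export
run_pipeline <- function(output_dir, seed = 1, input_csv = NULL,
                         cohort = cohort_config(),
                         modalities = MODALITIES,
                         model_families = c("constant", "regression", "net"),
                         control = net_control(),
                         hc = haigis_constants(), ec = eye_constants()) {
  stopifnot(length(modalities) >= 1, length(model_families) >= 1,
            all(modalities %in% MODALITIES),
            all(model_families %in% c("constant", "regression", "net")))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(stage) function(e) {
    unlink(written)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  }

  records <- tryCatch({
    if (is.null(input_csv)) {
      cohort$seed <- .derive_seed(seed, 1)
      generate_cohort(cohort, hc, ec)
    } else read_cohort_csv(input_csv)
  }, error = on_fail("cohort"))

  vec <- tryCatch(cohort_vectors(records, hc, ec),
                  error = on_fail("reconstruction"))
  split <- split_dataset(nrow(records), .derive_seed(seed, 2))

  y <- as.matrix(vec$recCP[, c("C0", "C45")])
  report <- list(); plot_rows <- list(); model_files <- character()
  for (m in modalities) {
    x <- as.matrix(vec[[m]][, c("C0", "C45")])
    fits <- list()
    for (fam in model_families) {
      fits[[fam]] <- tryCatch(switch(fam,
        constant   = fit_constant_model(x[split$train, ], y[split$train, ]),
        regression = fit_bivariate_regression(x[split$train, ],
                                              y[split$train, ]),
        net = {
          ctl <- control; ctl$seed <- .derive_seed(seed, 3)
          fit_shallow_net(x[split$train, ], y[split$train, ],
                          x[split$validation, ], y[split$validation, ],
                          control = ctl)
        }), error = on_fail(paste0("fit-", fam, "-", m)))
      mf <- file.path(output_dir, sprintf("model_%s_%s.json", m, fam))
      write_astig_model(fits[[fam]], mf)
      written <- c(written, mf); model_files <- c(model_files, mf)
    }
    for (sp in c("train", "test")) {
      idx <- if (sp == "train") split$train else split$test
      for (fam in c("none", model_families)) {
        mod <- if (fam == "none") NULL else fits[[fam]]
        row <- tryCatch(evaluate_predictions(mod, x[idx, ], y[idx, ]),
                        error = on_fail(paste0("evaluate-", fam, "-", m)))
        report[[length(report) + 1]] <-
          cbind(data.frame(modality = m, model = fam, split = sp), row)
        pred <- if (is.null(mod)) x[idx, ] else predict(mod, x[idx, ])
        err <- y[idx, ] - pred
        ell <- tryCatch(ellipse_points(error_ellipse_95(err)),
                        error = function(e) NULL)
        plot_rows[[length(plot_rows) + 1]] <- rbind(
          data.frame(modality = m, model = fam, split = sp, type = "point",
                     C0 = err[, 1], C45 = err[, 2]),
          if (!is.null(ell))
            data.frame(modality = m, model = fam, split = sp,
                       type = "ellipse", C0 = ell$C0, C45 = ell$C45))
      }
    }
  }
  report <- do.call(rbind, report)
  plot_data <- do.call(rbind, plot_rows)

  paths <- file.path(output_dir, c("report.csv", "report.json",
                                   "plot_data.csv", "run_log.json",
                                   "cohort.csv"))
  tryCatch({
    utils::write.csv(report, paths[1], row.names = FALSE)
    jsonlite::write_json(report, paths[2], dataframe = "rows", digits = NA)
    utils::write.csv(plot_data, paths[3], row.names = FALSE)
    jsonlite::write_json(list(
      seed = seed,
      sub_seeds = list(cohort = .derive_seed(seed, 1),
                       split = .derive_seed(seed, 2),
                       net = .derive_seed(seed, 3)),
      n = nrow(records),
      split_sizes = lengths(split[c("train", "validation", "test")]),
      modalities = modalities, model_families = model_families,
      package_version = as.character(utils::packageVersion("astigmap")),
      r_version = R.version.string),
      paths[4], auto_unbox = TRUE, pretty = TRUE)
    write_cohort_csv(records, paths[5])
  }, error = on_fail("report"))

  invisible(report)
}

#' Apply a published correction model to measured corneal astigmatism
#'
#' Implements the clinical recipe: decompose the measured reading into
#' (C0, C45), mirror left eyes into the right-eye frame, apply the
#' published regression model for the modality, mirror back, and convert
#' the predicted astigmatism to standard cylinder notation.
#'
#' @param records cohort data frame or CSV path carrying at least
#'   `laterality` and the modality's `{m}_flat_D`, `{m}_flat_axis_deg`,
#'   `{m}_steep_D` columns.
#' @param modality one of IOLMK, GK, TCP2, CorT, CorTTP.
#' @param form `"plus"` or `"minus"` cylinder form of the output.
#' @param model optional replacement `astig_model` (defaults to the
#'   published regression for the modality).
#' @return data frame with the predicted astigmatism per eye: `pred_C0`,
#'   `pred_C45` (physical frame), `pred_cyl_D`, `pred_axis_deg`,
#'   `pred_magnitude_D`.
#' @export
apply_published_correction <- function(records, modality,
                                       form = c("minus", "plus"),
                                       model = NULL) {
  form <- match.arg(form)
  if (!modality %in% MODALITIES)
    stop("unknown modality '", modality, "'; valid: ",
         paste(MODALITIES, collapse = ", "), call. = FALSE)
  if (is.character(records)) records <- read_cohort_csv(records)
  if (is.null(model)) model <- published_models()[[modality]]
  pv <- meridional_to_vector(records[[paste0(modality, "_flat_D")]],
                             records[[paste0(modality, "_flat_axis_deg")]],
                             records[[paste0(modality, "_steep_D")]])
  x <- cbind(C0 = pv$C0,
             C45 = mirror_to_right_eye(pv$C45, records$laterality))
  pred <- predict(model, x)
  pred[, 2] <- mirror_to_right_eye(pred[, 2], records$laterality)
  sc <- vector_to_sphero(0, pred[, 1], pred[, 2], form = form)
  data.frame(id = if (!is.null(records$id)) records$id
             else seq_len(nrow(records)),
             laterality = records$laterality,
             pred_C0 = pred[, 1], pred_C45 = pred[, 2],
             pred_cyl_D = sc$cylinder, pred_axis_deg = sc$axis,
             pred_magnitude_D = sqrt(pred[, 1]^2 + pred[, 2]^2))
}
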