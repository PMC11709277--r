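# ---- synthetic pseudophakic cohort -------------------------------------
#
# Generates study-like cohorts so the whole pipeline is testable without
# patient data.  Biometry follows truncated normals with the cohort means /
# SDs of a typical cataract population; the true corneal astigmatism vector
# is bivariate normal; each measurement modality is linked to the truth by
# inverting a fixed reference regression, so that refitting the regression
# on generated data is a parameter-recovery exercise with known ground
# truth.

#' Corneal astigmatism measurement modalities
#'
#' Names of the five supported readings: IOLMaster 700 keratometry, Galilei
#' G4 keratometry, total corneal power, and the area-integrated
#' front-surface and total corneal powers.
#' @export
MODALITIES <- c("IOLMK", "GK", "TCP2", "CorT", "CorTTP")

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the marginal distributions of a pseudophakic cataract
#' cohort: axial length 24.03 +/- 1.45 mm, anterior chamber depth
#' 3.32 +/- 0.40 mm, lens thickness 4.58 +/- 0.46 mm, corneal diameter
#' 12.02 +/- 0.55 mm; corneal equivalent power 43.0 +/- 1.5 dpt and
#' reconstructed-cornea astigmatism vector with mean (-0.3149, -0.0498) and
#' SDs (0.6706, 0.4482) dpt.  Each modality reading is the fixed reference
#' regression inverted at the true vector plus isotropic measurement noise.
#'
#' @param n cohort size (>= 10).
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param biometry list of `c(mean, sd, lower, upper)` per biometric field.
#' @param cornea_eq `c(mean, sd)` of the true corneal equivalent power, dpt.
#' @param astig list with `mean` (2-vector), `sd` (2-vector) and
#'   correlation `rho` of the true (C0, C45) vector, right-eye frame.
#' @param sigma_modality isotropic measurement noise SD per modality, dpt.
#' @param sigma_modality_eq noise SD of the modality equivalent power, dpt.
#' @param target_refraction aimed spherical equivalent, dpt.
#' @param quantize quantize refraction to clinical granularity
#'   (0.25 dpt sphere/cylinder, 5 degree axis)?
#' @param prob_os probability of a left (OS) eye.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n = 509, seed = 1,
                          biometry = list(
                            AL  = c(24.03, 1.45, 21, 30),
                            ACD = c(3.32, 0.40, 2.0, 5.0),
                            LT  = c(4.58, 0.46, 3.0, 6.0),
                            CD  = c(12.02, 0.55, 10.0, 14.0)),
                          cornea_eq = c(43.0, 1.5),
                          astig = list(mean = c(-0.3149, -0.0498),
                                       sd = c(0.6706, 0.4482), rho = 0),
                          sigma_modality = stats::setNames(
                            rep(0.1, 5), MODALITIES),
                          sigma_modality_eq = 0.25,
                          target_refraction = -0.25,
                          quantize = TRUE,
                          prob_os = 0.5) {
  stopifnot(n >= 10, all(vapply(biometry, function(b) b[2] > 0, TRUE)),
            cornea_eq[2] > 0, all(astig$sd > 0), abs(astig$rho) < 1,
            all(sigma_modality >= 0), sigma_modality_eq >= 0,
            prob_os >= 0, prob_os <= 1)
  if (is.null(names(sigma_modality)))
    names(sigma_modality) <- MODALITIES
  stopifnot(all(MODALITIES %in% names(sigma_modality)))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 biometry = biometry, cornea_eq = cornea_eq, astig = astig,
                 sigma_modality = sigma_modality,
                 sigma_modality_eq = sigma_modality_eq,
                 target_refraction = target_refraction,
                 quantize = isTRUE(quantize), prob_os = prob_os),
            class = "cohort_config")
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

.round_step <- function(x, step) round(x / step) * step

# IOL power giving the target spherical-equivalent refraction for a
# spherical-equivalent cornea (exact inversion of the vergence chain)
.solve_iolp <- function(cornea_eq, AL, ELP, target, ec) {
  v2 <- transfer_vergence(ec$lane_vergence + target, ec$vertex_distance,
                          ec$n_air)
  v2_behind <- cornea_eq + v2
  v3 <- transfer_vergence(v2_behind, ELP / 1000, ec$n_A)
  retinal_vergence(AL, ELP, ec) - v3
}

#' Generate a synthetic pseudophakic cohort
#'
#' Draws biometry and a true corneal power vector per eye, chooses the IOL
#' power that targets the configured refraction (rounded to 0.5 dpt steps),
#' computes the exact postoperative refraction through the forward vergence
#' model (optionally quantized to clinical granularity), and produces the
#' five modality readings by inverting the fixed reference regressions at
#' the true astigmatism vector plus measurement noise.  Left eyes carry
#' physically mirrored (sign-flipped C45) measurements and refractions.
#'
#' @param cfg a [cohort_config()].
#' @param hc,ec model constants, see [haigis_constants()], [eye_constants()].
#' @return data frame in the cohort CSV schema (see [write_cohort_csv()]),
#'   with the unquantized ground truth attached as `attr(, "truth")`
#'   (columns: `id`, `EQ`, `C0`, `C45` in the right-eye frame, `ELP`,
#'   `ref_sphere`, `ref_cyl`, `ref_axis`).
#' @export
generate_cohort <- function(cfg = cohort_config(), hc = haigis_constants(),
                            ec = eye_constants()) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  n <- cfg$n

  bio <- lapply(cfg$biometry, function(b)
    .rtruncnorm(n, b[1], b[2], b[3], b[4]))
  laterality <- ifelse(stats::runif(n) < cfg$prob_os, "OS", "OD")

  eq_true <- stats::rnorm(n, cfg$cornea_eq[1], cfg$cornea_eq[2])
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- cfg$astig$rho
  c0_true <- cfg$astig$mean[1] + cfg$astig$sd[1] * z1
  c45_true <- cfg$astig$mean[2] +
    cfg$astig$sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  # truth is kept in the right-eye frame; the physical eye of an OS record
  # has the oblique component sign-flipped
  c45_phys <- mirror_to_right_eye(c45_true, laterality)

  elp <- haigis_elp(bio$ACD, bio$AL, hc)
  iolp <- .round_step(
    .solve_iolp(eq_true, bio$AL, elp, cfg$target_refraction, ec), 0.5)
  ref <- forward_refraction(eq_true, c0_true, c45_phys, bio$AL, elp, iolp, ec)
  ref_q <- ref
  if (cfg$quantize) {
    ref_q$sphere <- .round_step(ref$sphere, 0.25)
    ref_q$cylinder <- .round_step(ref$cylinder, 0.25)
    ref_q$axis <- normalize_axis(.round_step(ref$axis, 5))
    ref_q$axis[ref_q$cylinder == 0] <- 0
  }

  out <- data.frame(id = seq_len(n), laterality = laterality,
                    AL_mm = bio$AL, ACD_mm = bio$ACD, LT_mm = bio$LT,
                    CD_mm = bio$CD, IOLP_D = iolp,
                    ref_sphere_D = ref_q$sphere, ref_cyl_D = ref_q$cylinder,
                    ref_axis_deg = ref_q$axis)

  pub <- published_models()
  for (m in MODALITIES) {
    Ainv <- solve(pub[[m]]$A)
    xm <- t(Ainv %*% rbind(c0_true - pub[[m]]$b[1],
                           c45_true - pub[[m]]$b[2]))
    sig <- cfg$sigma_modality[[m]]
    xm <- xm + matrix(stats::rnorm(2 * n, 0, sig), n, 2)
    # back to the physical frame for OS eyes, then to meridional notation
    xm[, 2] <- mirror_to_right_eye(xm[, 2], laterality)
    eq_m <- eq_true + stats::rnorm(n, 0, cfg$sigma_modality_eq)
    sc <- vector_to_sphero(eq_m, xm[, 1], xm[, 2], form = "plus")
    out[[paste0(m, "_flat_D")]] <- sc$sphere
    out[[paste0(m, "_flat_axis_deg")]] <- sc$axis
    out[[paste0(m, "_steep_D")]] <- sc$sphere + sc$cylinder
  }

  attr(out, "truth") <- data.frame(
    id = out$id, EQ = eq_true, C0 = c0_true, C45 = c45_true, ELP = elp,
    ref_sphere = ref$sphere, ref_cyl = ref$cylinder, ref_axis = ref$axis)
  attr(out, "config") <- cfg
  out
}

.cohort_columns <- function() {
  c("id", "laterality", "AL_mm", "ACD_mm", "LT_mm", "CD_mm", "IOLP_D",
    "ref_sphere_D", "ref_cyl_D", "ref_axis_deg",
    as.vector(t(outer(MODALITIES, c("_flat_D", "_flat_axis_deg", "_steep_D"),
                      paste0))))
}

#' Write / read a cohort CSV
#'
#' The schema is one row per eye with columns `id`, `laterality` (OD/OS),
#' `AL_mm`, `ACD_mm`, `LT_mm`, `CD_mm`, `IOLP_D`, `ref_sphere_D`,
#' `ref_cyl_D`, `ref_axis_deg`, then `{m}_flat_D`, `{m}_flat_axis_deg`,
#' `{m}_steep_D` for each modality IOLMK, GK, TCP2, CorT, CorTTP.  The
#' round trip write-then-read is lossless (17 significant digits).
#'
#' @param records cohort data frame.
#' @param path CSV file path.
#' @return `path` invisibly (write); the cohort data frame (read).
#' @export
write_cohort_csv <- function(records, path) {
  miss <- setdiff(.cohort_columns(), names(records))
  if (length(miss))
    stop("cohort missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec <- records[, .cohort_columns()]
  num <- vapply(rec, is.numeric, TRUE) & names(rec) != "id"
  rec[num] <- lapply(rec[num], function(x) sprintf("%.17g", x))
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohort_columns(), names(rec))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(rec$laterality %in% c("OD", "OS")))
    stop("laterality must be OD or OS", call. = FALSE)
  ax_cols <- grep("axis", names(rec), value = TRUE)
  for (cl in ax_cols) {
    norm <- normalize_axis(rec[[cl]])
    if (any(norm != rec[[cl]])) {
      warning("normalized out-of-range axes in column ", cl, call. = FALSE)
      rec[[cl]] <- norm
    }
  }
  rec
}

#' Power-vector view of a cohort
#'
#' Decomposes the refraction and all modality readings of a cohort into
#' double-angle power-vector components, mirrored into the right-eye frame,
#' and reconstructs the corneal power vector per eye.
#'
#' @param records cohort data frame (see [write_cohort_csv()] schema).
#' @param hc,ec model constants.
#' @return list with elements `recCP` (data frame EQ/C0/C45) and one data
#'   frame per modality (EQ/C0/C45), all in the right-eye frame.
#' @export
cohort_vectors <- function(records, hc = haigis_constants(),
                           ec = eye_constants()) {
  rec <- data.frame(laterality = records$laterality, AL = records$AL_mm,
                    ACD = records$ACD_mm, IOLP = records$IOLP_D,
                    ref_sphere = records$ref_sphere_D,
                    ref_cyl = records$ref_cyl_D,
                    ref_axis = records$ref_axis_deg)
  out <- list(recCP = reconstruct_corneal_power(rec, hc, ec))
  for (m in MODALITIES) {
    pv <- meridional_to_vector(records[[paste0(m, "_flat_D")]],
                               records[[paste0(m, "_flat_axis_deg")]],
                               records[[paste0(m, "_steep_D")]])
    pv$C45 <- mirror_to_right_eye(pv$C45, records$laterality)
    out[[m]] <- pv
  }
  out
}
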