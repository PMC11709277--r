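#' astigmap: corneal astigmatism reconstruction and prediction
#'
#' Power-vector arithmetic, a paraxial pseudophakic eye model, prediction
#' models mapping measured corneal astigmatism to reconstructed corneal
#' power, double-angle vector statistics, and a synthetic cohort generator.
#'
#' @keywords internal
"_PACKAGE"

# ---- power-vector conversions ------------------------------------------
#
# Convention used throughout: full-cylinder projections
#   C0  = C * cos(2 * axis),  C45 = C * sin(2 * axis)
# (not the half-magnitude Jackson-cross J0/J45).  With-the-rule astigmatism
# (steep meridian near 90 degrees) then has C0 > 0.  Axes are in degrees,
# normalised to [0, 180); the cylinder's power acts at axis + 90.

DEG <- pi / 180

#' Normalise an axis to [0, 180) degrees
#'
#' @param axis numeric vector of axes in degrees.
#' @return numeric vector in `[0, 180)`.
#' @export
normalize_axis <- function(axis) {
  ((axis %% 180) + 180) %% 180
}

.check_finite <- function(..., what = "input") {
  vals <- c(...)
  if (!all(is.finite(vals)))
    stop("non-finite ", what, " value", call. = FALSE)
  invisible(TRUE)
}

#' Decompose a spherocylinder into power-vector components
#'
#' Converts standard sphere/cylinder/axis notation (plus- or minus-cylinder
#' form) into the double-angle power vector (EQ, C0, C45), where EQ is the
#' spherical equivalent and C0/C45 are the full-cylinder projections onto
#' the 0/90 and 45/135 degree meridians.
#'
#' @param sphere sphere in dioptres.
#' @param cylinder signed cylinder in dioptres.
#' @param axis cylinder axis in degrees (normalised mod 180).
#' @return data frame with columns `EQ`, `C0`, `C45` (dioptres).
#' @examples
#' sphero_to_vector(0, -1, 0)      # EQ -0.5, C0 -1, C45 0
#' sphero_to_vector(-1, 2, 45)     # EQ 0, C0 0, C45 2
#' @export
sphero_to_vector <- function(sphere, cylinder, axis) {
  .check_finite(sphere, cylinder, axis, what = "spherocylinder")
  axis <- normalize_axis(axis)
  data.frame(
    EQ  = sphere + cylinder / 2,
    C0  = cylinder * cos(2 * axis * DEG),
    C45 = cylinder * sin(2 * axis * DEG)
  )
}

#' Decompose keratometry-style meridional powers into power-vector components
#'
#' Takes the power in the flat meridian, the axis of the flat meridian, and
#' the power in the steep meridian (the convention in which keratometry and
#' total-corneal-power readings are exported) and returns (EQ, C0, C45).
#' Equivalent to the plus-cylinder spherocylinder with sphere = flat power,
#' cylinder = steep - flat, axis = flat meridian.
#'
#' @param power_flat dioptric power in the flat meridian.
#' @param axis_flat axis of the flat meridian in degrees.
#' @param power_steep dioptric power in the steep meridian
#'   (must be >= `power_flat`).
#' @return data frame with columns `EQ`, `C0`, `C45`.
#' @examples
#' meridional_to_vector(42, 0, 44)   # with-the-rule: C0 = +2
#' @export
meridional_to_vector <- function(power_flat, axis_flat, power_steep) {
  .check_finite(power_flat, axis_flat, power_steep, what = "meridional power")
  if (any(power_steep < power_flat))
    stop("power_steep must be >= power_flat", call. = FALSE)
  sphero_to_vector(power_flat, power_steep - power_flat, axis_flat)
}

#' Convert a power vector back to spherocylindrical notation
#'
#' Inverse of [sphero_to_vector()].  The astigmatism magnitude is
#' `A = sqrt(C0^2 + C45^2)`; in plus-cylinder form the cylinder is `+A` at
#' axis `atan2(C45, C0) / 2` (mod 180) and the sphere is `EQ - A/2`; the
#' minus-cylinder form is the usual transposition.
#'
#' @param EQ spherical equivalent (dioptres).
#' @param C0,C45 astigmatism projections (dioptres).
#' @param form `"plus"` or `"minus"` cylinder form.
#' @return data frame with columns `sphere`, `cylinder`, `axis`.
#' @examples
#' vector_to_sphero(43, 1.8794, 0.6840)          # ~ 42 / +2 x 10
#' vector_to_sphero(0, -1, 0, form = "minus")    # 0 / -1 x 0
#' @export
vector_to_sphero <- function(EQ, C0, C45, form = c("plus", "minus")) {
  form <- match.arg(form)
  .check_finite(EQ, C0, C45, what = "power vector")
  A <- sqrt(C0^2 + C45^2)
  axis_plus <- normalize_axis(atan2(C45, C0) / 2 / DEG)
  axis_plus[A == 0] <- 0
  if (form == "plus") {
    out <- data.frame(sphere = EQ - A / 2, cylinder = A, axis = axis_plus)
  } else {
    axis_minus <- normalize_axis(axis_plus + 90)
    axis_minus[A == 0] <- 0
    out <- data.frame(sphere = EQ + A / 2, cylinder = -A, axis = axis_minus)
  }
  out
}

#' Defocus equivalent of a refraction power vector
#'
#' Scalar blur metric `DEQ = sqrt(EQ^2 + C0^2/4 + C45^2/4)` in dioptres.
#' Always >= |EQ|, with equality iff the astigmatism is zero.
#'
#' @inheritParams vector_to_sphero
#' @return numeric vector of defocus equivalents (dioptres).
#' @export
defocus_equivalent <- function(EQ, C0, C45) {
  .check_finite(EQ, C0, C45, what = "power vector")
  sqrt(EQ^2 + C0^2 / 4 + C45^2 / 4)
}

#' Mirror power vectors of left eyes into the right-eye frame
#'
#' To pool left (OS) and right (OD) eyes in one model, the oblique component
#' C45 is flipped in sign for left eyes; right eyes pass through unchanged.
#' Applying the operation twice restores the input (involution).
#'
#' @param C45 oblique astigmatism component(s), dioptres.
#' @param laterality character vector of `"OD"` / `"OS"`.
#' @return C45 with the sign flipped where `laterality == "OS"`.
#' @export
mirror_to_right_eye <- function(C45, laterality) {
  if (!all(laterality %in% c("OD", "OS")))
    stop("laterality must be 'OD' or 'OS'", call. = FALSE)
  C45 * (1 - 2 * (laterality == "OS"))
}
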