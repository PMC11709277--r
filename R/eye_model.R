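# ---- paraxial pseudophakic eye model -----------------------------------
#
# Simplified pseudophakic eye with three refracting elements: a thin-lens
# spectacle correction at the vertex distance in front of the cornea, a
# thin-lens (spherocylindrical) cornea, and a thin-lens IOL at the effective
# lens position (ELP) behind the corneal front vertex.  All vergence
# arithmetic is done per principal meridian with distances in metres;
# biometry is supplied in millimetres as measured.

#' Optical constants of the pseudophakic eye model
#'
#' @param n_air refractive index of air.
#' @param n_A refractive index of the aqueous humour.
#' @param n_V refractive index of the vitreous humour.
#' @param vertex_distance spectacle vertex distance in metres.
#' @param lane_vergence vergence directly in front of the spectacle plane in
#'   dioptres; `-1/6` dpt corresponds to a 6 m refraction lane.
#' @return list of class `eye_constants`.
#' @export
eye_constants <- function(n_air = 1.0, n_A = 1.336, n_V = 1.336,
                          vertex_distance = 0.012, lane_vergence = -1 / 6) {
  stopifnot(n_air > 0, n_A > 1, n_V > 1, vertex_distance > 0)
  structure(list(n_air = n_air, n_A = n_A, n_V = n_V,
                 vertex_distance = vertex_distance,
                 lane_vergence = lane_vergence),
            class = "eye_constants")
}

#' Haigis formula constants
#'
#' Defaults are the IOLCon-optimised constants for the MX60P lens.
#'
#' @param a0 intercept (mm).
#' @param a1 weight for the anterior chamber depth ACD.
#' @param a2 weight for the axial length AL.
#' @return list of class `haigis_constants`.
#' @export
haigis_constants <- function(a0 = 0.1835, a1 = 0.3153, a2 = 0.1725) {
  .check_finite(a0, a1, a2, what = "Haigis constant")
  structure(list(a0 = a0, a1 = a1, a2 = a2), class = "haigis_constants")
}

#' Effective lens position from the Haigis regression
#'
#' `ELP = a0 + a1 * ACD + a2 * AL`, all lengths in millimetres.
#'
#' @param ACD anterior chamber depth in mm (epithelium to lens apex).
#' @param AL axial length in mm.
#' @param hc [haigis_constants()].
#' @return effective lens position in mm.
#' @examples
#' haigis_elp(3.32, 24.03)   # 5.3755 mm
#' @export
haigis_elp <- function(ACD, AL, hc = haigis_constants()) {
  .check_finite(ACD, AL, what = "biometry")
  hc$a0 + hc$a1 * ACD + hc$a2 * AL
}

#' Vergence at the IOL plane of a pencil focusing on the retina
#'
#' The reciprocal of the reduced distance from the ELP plane to the retina:
#' `n_V / ((AL - ELP) / 1000)` in dioptres.
#'
#' @param AL axial length in mm.
#' @param ELP effective lens position in mm; must be < `AL`.
#' @param ec [eye_constants()].
#' @return vergence in dioptres.
#' @export
retinal_vergence <- function(AL, ELP, ec = eye_constants()) {
  .check_finite(AL, ELP, what = "geometry")
  if (any(AL <= ELP))
    stop("axial length must exceed the effective lens position", call. = FALSE)
  ec$n_V / ((AL - ELP) / 1000)
}

#' Transfer a vergence between planes
#'
#' `v' = v / (1 - v * distance / index)`.  The distance is signed: positive
#' propagates in the direction of light, negative transfers backwards.
#'
#' @param v vergence(s) in dioptres.
#' @param distance signed distance in metres.
#' @param index refractive index of the medium.
#' @return transferred vergence(s) in dioptres.
#' @export
transfer_vergence <- function(v, distance, index) {
  .check_finite(v, distance, index, what = "vergence transfer")
  den <- 1 - v * distance / index
  if (any(abs(den) < 1e-12))
    stop("vergence focuses at the target plane (zero denominator)",
         call. = FALSE)
  v / den
}

#' Spectacle-plane vergence traced to the corneal front vertex
#'
#' Adds the lane vergence to the meridional powers of the spectacle
#' refraction and transfers the result through the vertex distance in air.
#' Principal axes are preserved (meridian 1 at the cylinder axis, meridian 2
#' orthogonal).
#'
#' @param sphere,cylinder,axis spectacle refraction (dioptres / degrees).
#' @param ec [eye_constants()].
#' @return data frame with columns `v_m1`, `v_m2`, `axis_m1`.
#' @export
spectacle_vergence_at_cornea <- function(sphere, cylinder, axis,
                                         ec = eye_constants()) {
  .check_finite(sphere, cylinder, axis, what = "refraction")
  axis <- normalize_axis(axis)
  # cylinder power acts at axis + 90: meridian at `axis` sees the sphere only
  p1 <- sphere
  p2 <- sphere + cylinder
  v1 <- transfer_vergence(ec$lane_vergence + p1, ec$vertex_distance, ec$n_air)
  v2 <- transfer_vergence(ec$lane_vergence + p2, ec$vertex_distance, ec$n_air)
  data.frame(v_m1 = v1, v_m2 = v2, axis_m1 = axis)
}

# spherical vergence just behind the cornea implied by AL, ELP and IOLP:
# retinal vergence minus IOL power, transferred backwards through the
# aqueous to the corneal front vertex plane
.vergence_behind_cornea <- function(AL, ELP, IOLP, ec) {
  v3 <- retinal_vergence(AL, ELP, ec) - IOLP
  transfer_vergence(v3, -ELP / 1000, ec$n_A)
}

#' Reconstruct corneal power from pseudophakic refraction and biometry
#'
#' Runs the paraxial vergence chain per principal meridian: the ELP is
#' predicted with the Haigis regression, the vergence of a pencil focusing
#' on the retina is taken at the IOL plane, the (spherical, non-toric) IOL
#' power is subtracted and the result transferred backwards to the corneal
#' front vertex; the spectacle refraction plus lane vergence is traced
#' forwards through the vertex distance.  The reconstructed corneal power is
#' the meridional difference of the two, decomposed into power-vector
#' components, with C45 mirrored into the right-eye frame for left eyes.
#'
#' @param records data frame with columns `laterality` ("OD"/"OS"), `AL`,
#'   `ACD` (mm), `IOLP` (dpt), `ref_sphere`, `ref_cyl` (dpt), `ref_axis`
#'   (degrees).
#' @param hc [haigis_constants()].
#' @param ec [eye_constants()].
#' @return data frame with columns `EQ`, `C0`, `C45` (dioptres, right-eye
#'   frame).
#' @examples
#' rec <- data.frame(laterality = "OD", AL = 24.03, ACD = 3.32,
#'                   IOLP = 20.3, ref_sphere = -0.25, ref_cyl = 0,
#'                   ref_axis = 0)
#' reconstruct_corneal_power(rec)   # EQ ~ 42.95 dpt
#' @export
reconstruct_corneal_power <- function(records, hc = haigis_constants(),
                                      ec = eye_constants()) {
  need <- c("laterality", "AL", "ACD", "IOLP",
            "ref_sphere", "ref_cyl", "ref_axis")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  elp <- haigis_elp(records$ACD, records$AL, hc)
  v2b <- .vergence_behind_cornea(records$AL, elp, records$IOLP, ec)
  v2 <- spectacle_vergence_at_cornea(records$ref_sphere, records$ref_cyl,
                                     records$ref_axis, ec)
  p1 <- v2b - v2$v_m1   # corneal power along the refraction cylinder axis
  p2 <- v2b - v2$v_m2
  pv <- sphero_to_vector(p1, p2 - p1, v2$axis_m1)
  pv$C45 <- mirror_to_right_eye(pv$C45, records$laterality)
  pv
}

#' Forward refraction of a pseudophakic eye with a known cornea
#'
#' Exact inverse of the reconstruction chain: given the corneal power vector
#' (physical orientation, no left-eye mirroring), axial length, ELP and IOL
#' power, computes the spectacle refraction per principal meridian of the
#' cornea and returns it in minus-cylinder form.
#'
#' @param EQ,C0,C45 corneal power vector (dioptres).
#' @param AL axial length (mm).
#' @param ELP effective lens position (mm).
#' @param IOLP IOL power (dpt).
#' @param ec [eye_constants()].
#' @return data frame with columns `sphere`, `cylinder` (<= 0), `axis`.
#' @export
forward_refraction <- function(EQ, C0, C45, AL, ELP, IOLP,
                               ec = eye_constants()) {
  .check_finite(EQ, C0, C45, AL, ELP, IOLP, what = "forward model")
  v2b <- .vergence_behind_cornea(AL, ELP, IOLP, ec)
  A <- sqrt(C0^2 + C45^2)
  axis_flat <- normalize_axis(atan2(C45, C0) / 2 / DEG)
  axis_flat[A == 0] <- 0
  p_flat <- EQ - A / 2
  p_steep <- EQ + A / 2
  # vergence in front of the cornea per corneal principal meridian, then
  # backwards through the vertex distance to the spectacle plane
  r1 <- transfer_vergence(v2b - p_flat, -ec$vertex_distance, ec$n_air) -
    ec$lane_vergence
  r2 <- transfer_vergence(v2b - p_steep, -ec$vertex_distance, ec$n_air) -
    ec$lane_vergence
  pv <- sphero_to_vector(r1, r2 - r1, axis_flat)
  vector_to_sphero(pv$EQ, pv$C0, pv$C45, form = "minus")
}
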