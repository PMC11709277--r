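# paraxial pseudophakic eye model

test_that("Haigis ELP regression reproduces worked values", {
  expect_close(haigis_elp(3.32, 24.03), 5.375471, tol = 1e-6)
  expect_equal(haigis_elp(0, 0), 0.1835)
  expect_close(haigis_elp(4.05, 27.71),
               0.1835 + 0.3153 * 4.05 + 0.1725 * 27.71, tol = 1e-12)
})

test_that("retinal vergence is the reciprocal reduced distance", {
  expect_close(retinal_vergence(24.03, 5.375471), 1.336 / 0.018654529,
               tol = 1e-4)
  expect_close(retinal_vergence(5 + 1336, 5), 1.0, tol = 1e-12)
  expect_close(retinal_vergence(26, 5), 1.336 / 0.021, tol = 1e-9)
  expect_error(retinal_vergence(5, 6), "axial length")
})

test_that("vergence transfer handles sign, zero and singular cases", {
  expect_equal(transfer_vergence(0, 0.5, 1.336), 0)
  expect_close(transfer_vergence(51.318, -0.0053755, 1.336),
               51.318 / (1 + 51.318 * 0.0053755 / 1.336), tol = 1e-9)
  expect_close(transfer_vergence(-1 / 2.4, 0.012, 1),
               (-1 / 2.4) / (1 + 0.012 / 2.4), tol = 1e-12)
  # forward then backward transfer is the identity
  v <- c(-5, 0.5, 20, 60)
  expect_close(transfer_vergence(transfer_vergence(v, 0.01, 1.336),
                                 -0.01, 1.336), v, tol = 1e-10)
  expect_error(transfer_vergence(100, 0.01, 1), "zero denominator")
})

test_that("spectacle vergence at the cornea traces both meridians", {
  z <- spectacle_vergence_at_cornea(0, 0, 0)
  expect_close(z$v_m1, (-1 / 6) / (1 + (1 / 6) * 0.012), tol = 1e-9)
  expect_equal(z$v_m1, z$v_m2)
  z <- spectacle_vergence_at_cornea(0, -1, 0)
  expect_close(z$v_m2, (-1 / 6 - 1) / (1 + (1 / 6 + 1) * 0.012), tol = 1e-9)
  z <- spectacle_vergence_at_cornea(10, 0, 0)
  expect_close(z$v_m1, (10 - 1 / 6) / (1 - (10 - 1 / 6) * 0.012), tol = 1e-6)
})

test_that("reconstruction matches the independent forward-trace oracle", {
  rec <- data.frame(laterality = "OD", AL = 24.03, ACD = 3.32, IOLP = 20.3,
                    ref_sphere = -0.25, ref_cyl = 0, ref_axis = 0)
  pv <- reconstruct_corneal_power(rec)
  expect_close(pv$EQ, 42.9499, tol = 1e-3)
  expect_identical(pv$C0, 0); expect_identical(pv$C45, 0)
  elp <- haigis_elp(3.32, 24.03)
  expect_close(pv$EQ, oracle_corneal_power(-0.25, 24.03, elp, 20.3),
               tol = 1e-8)

  # astigmatic refraction: each principal meridian independently
  rec$ref_sphere <- 0; rec$ref_cyl <- -1
  pv <- reconstruct_corneal_power(rec)
  p_flat <- oracle_corneal_power(0, 24.03, elp, 20.3)     # meridian 0
  p_steep <- oracle_corneal_power(-1, 24.03, elp, 20.3)   # meridian 90
  expect_close(pv$EQ, (p_flat + p_steep) / 2, tol = 1e-8)
  expect_close(pv$C0, p_steep - p_flat, tol = 1e-8)       # axis 0: C0 = +diff
  expect_close(pv$C0, 0.9843, tol = 1e-3)
  expect_equal(pv$C45, 0)
})

test_that("forward refraction inverts the reconstruction chain", {
  elp <- haigis_elp(3.32, 24.03)
  fr <- forward_refraction(42.9499, 0, 0, 24.03, elp, 20.3)
  expect_close(fr$sphere, -0.25, tol = 2e-3)
  expect_equal(fr$cylinder, 0)
})

random_records <- function(n, seed) {
  set.seed(seed)
  AL <- runif(n, 21, 28); ACD <- runif(n, 2.2, 4.5)
  elp <- haigis_elp(ACD, AL)
  # physiologic IOL power: the rounded power targeting the refraction for a
  # plausible corneal equivalent power
  eqc <- runif(n, 40, 46)
  target <- round(runif(n, -2, 0.5) * 4) / 4
  v2 <- transfer_vergence(-1 / 6 + target, 0.012, 1)
  v3 <- transfer_vergence(eqc + v2, elp / 1000, 1.336)
  iolp <- round((retinal_vergence(AL, elp) - v3) * 2) / 2
  data.frame(
    laterality = sample(c("OD", "OS"), n, replace = TRUE),
    AL = AL, ACD = ACD, IOLP = iolp,
    ref_sphere = target,
    ref_cyl = -round(runif(n, 0, 3) * 4) / 4,
    ref_axis = runif(n, 0, 180))
}

test_that("forward and inverse chains round-trip over random eyes", {
  n <- 1e4
  rec <- random_records(n, 21)
  pv <- reconstruct_corneal_power(rec)
  # physiologic sanity band for the reconstructed equivalent power
  expect_true(all(pv$EQ > 35 & pv$EQ < 55))
  # forward model needs the physical (unmirrored) orientation
  c45_phys <- mirror_to_right_eye(pv$C45, rec$laterality)
  elp <- haigis_elp(rec$ACD, rec$AL)
  fr <- forward_refraction(pv$EQ, pv$C0, c45_phys, rec$AL, elp, rec$IOLP)
  v_in <- sphero_to_vector(rec$ref_sphere, rec$ref_cyl, rec$ref_axis)
  v_out <- sphero_to_vector(fr$sphere, fr$cylinder, fr$axis)
  expect_close(as.matrix(v_out), as.matrix(v_in), tol = 1e-9)
})

test_that("zero refractive cylinder gives exactly stigmatic recCP", {
  rec <- random_records(500, 31)
  rec$ref_cyl <- 0
  pv <- reconstruct_corneal_power(rec)
  expect_true(all(pv$C0 == 0 & pv$C45 == 0))
})

test_that("reconstruction commutes with left/right mirroring", {
  rec <- random_records(300, 41)
  mir <- rec
  mir$laterality <- ifelse(rec$laterality == "OD", "OS", "OD")
  mir$ref_axis <- normalize_axis(-rec$ref_axis)   # physically mirrored eye
  a <- reconstruct_corneal_power(rec)
  b <- reconstruct_corneal_power(mir)
  expect_close(as.matrix(a), as.matrix(b), tol = 1e-9)
})
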