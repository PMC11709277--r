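# Independent oracles used across the suite.

# Meridional-power oracle for the double-angle decomposition: the power of
# a spherocylinder (S, C, axis) along meridian theta is
#   m(theta) = S + C * sin^2(theta - axis)
# and the power-vector components follow from a harmonic regression
#   m(theta) = EQ - (C0/2) cos(2 theta) - (C45/2) sin(2 theta).
oracle_vector_from_meridians <- function(sphere, cylinder, axis) {
  th <- (0:179) * pi / 180
  m <- sphere + cylinder * sin(th - axis * pi / 180)^2
  fit <- stats::lm(m ~ cos(2 * th) + sin(2 * th))
  c(EQ = unname(coef(fit)[1]), C0 = unname(-2 * coef(fit)[2]),
    C45 = unname(-2 * coef(fit)[3]))
}

# Forward-trace oracle for the eye model: propagates a pencil from the
# 6 m lane through spectacle, cornea and IOL and finds, by root search, the
# corneal meridional power that puts the focus on the retina.  Independent
# of the package's analytic inversion (forward simulation + uniroot).
oracle_corneal_power <- function(spectacle_power, AL, ELP, IOLP,
                                 n_A = 1.336, n_V = 1.336) {
  focus_miss <- function(P) {
    v <- -1 / 6 + spectacle_power             # behind the spectacle
    v <- v / (1 - v * 0.012)                  # 12 mm air to the cornea
    v <- v + P                                # behind the cornea
    v <- v / (1 - v * (ELP / 1000) / n_A)     # aqueous to the IOL plane
    v <- v + IOLP                             # behind the IOL
    n_V / v * 1000 - (AL - ELP)               # focus distance minus retina
  }
  stats::uniroot(focus_miss, c(20, 70), tol = 1e-12)$root
}

# cohort used by several files: modest size, no measurement noise and no
# quantization so the analytic structure is exactly identifiable
noise_free_config <- function(n = 300, seed = 42) {
  cohort_config(n = n, seed = seed, quantize = FALSE,
                sigma_modality = stats::setNames(rep(0, 5), MODALITIES),
                sigma_modality_eq = 0)
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_lt(max(abs(object - expected)), tol)
}
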