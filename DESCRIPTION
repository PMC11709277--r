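Package: astigmap
Title: Corneal Astigmatism Reconstruction and Prediction for Toric IOL Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs corneal spherocylindrical power from pseudophakic
    spectacle refraction, biometry and implanted lens power through a paraxial
    vergence chain (Haigis effective lens position, per-meridian vergence
    transfer), and maps measured corneal astigmatism power-vector components
    (keratometry and total corneal power modalities) to the reconstructed
    astigmatism with constant-centroid, bivariate linear regression, and
    shallow feedforward neural network models.  Evaluation uses double-angle
    vector statistics: centroids, 95% error ellipses from variance-covariance
    matrices, mean vector difference and mean squared prediction error.  A
    seeded synthetic-cohort generator provides study-like pseudophakic data
    for end-to-end testing and parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
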