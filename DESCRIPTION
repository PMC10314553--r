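Package: airwaymorph
Title: Upper-Airway Volumetrics and Mandibular Kinematics from CBCT Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Plane-delimited oropharyngeal volumetrics and mandibular pitch
    kinematics for registered cone-beam CT (CBCT) airway segmentations.
    Reads NIfTI binary masks and 3D Slicer fiducial files into a common
    RAS millimetre frame, builds the Frankfurt/midsagittal/transporionic
    head orientation, registers timepoints rigidly (landmark least-squares
    or masked voxel-based optimisation), delimits total, superior and
    inferior oropharynx by parallel planes through the Ba-PNS, C2I and C4S
    levels, and measures region volumes and cap-free surface areas. Also
    computes signed mandibular pitch rotations and B-point displacement,
    intra-rater reliability (Dahlberg error, relative random error, ICC),
    and a paired-design cohort statistics layer (Student/paired t,
    Lilliefors-corrected normality, age-adjusted ANCOVA, Pearson
    correlation, chi-square, noncentral-t sample size, treatment-success
    classification). Ships synthetic phantom generators with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    MASS,
    car,
    generics,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    withr
Config/testthat/edition: 3
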