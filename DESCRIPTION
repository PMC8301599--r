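Package: lvkin
Title: Left-Ventricular Wall Kinematics from 4D Cardiac Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts murine left-ventricular endo- and epi-cardial wall
    kinematics from 4D cine ultrasound. Boundaries are parameterized by 48
    anchor-point radii (6 rotations x 2 boundaries x 4 short-axis slices);
    three principal-component image-regression models with a periodic
    B-spline basis over the cardiac cycle predict the radii, which are then
    interpolated into a standardized 60 x 60 x 60 4D surface mesh. From the
    mesh the package derives Lagrangian circumferential and longitudinal
    strain, early/late systolic and diastolic strain rates, and global
    function metrics (volumes, stroke volume, ejection fraction). A
    synthetic beating-LV speckle phantom with known ground truth and a
    Monte Carlo cross-validation harness make the whole pipeline testable
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
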