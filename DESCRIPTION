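Package: gaitwrench
Title: Ground Reaction Force and Moment Prediction from Body-Segment
    Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts the three-dimensional ground reaction forces and
    moments acting on each foot during walking, using only rigid-body
    segment kinematics such as those produced by inertial motion capture.
    Implements a scaled 16-segment anthropometric body model, Newton-Euler
    computation of the total external wrench, velocity-threshold gait event
    detection, a smooth-transition-assumption distribution of the wrench
    between the feet during double support, centre-of-pressure and
    frictional-torque recovery, and a curve-comparison metric suite (RMSE,
    relative RMSE, Pearson correlation categories, Sprague-Geers magnitude
    and phase). A synthetic-gait generator with exactly known ground truth
    makes every pipeline stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
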