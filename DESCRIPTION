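Package: gcderiv
Title: Time-Derivative Analysis of Microplate Growth and Fluorescence Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates bacterial growth from multimode microplate-reader
    measurements using the time derivatives of optical density (OD600) and
    bulk fluorescence (FL) curves. Implements a coupled ODE model of
    dormant-to-active logistic growth and GFP expression, maturation and
    saturable degradation; forward-difference derivatives with Hanning
    smoothing; bell-shaped derivative-peak extraction (location, height,
    width); modified Gompertz (Zwietering) lag-time fitting; single-parameter
    sweeps with power-law, linear, exponential and Michaelis-Menten relation
    fits; plate-reader CSV import with path-length correction and replicate
    aggregation; and a synthetic plate-data generator with known ground truth
    for validating the full analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
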