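Package: coretemp
Title: Non-Invasive Core Body Temperature Prediction from Wearable Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating rectal (core body) temperature from
    non-invasive wearable measurements: skin temperatures (insulated and
    non-insulated), skin heat fluxes, and heart rate, sampled at 0.1 Hz
    during heat-stress protocols. Implements the published "Max-Input"
    (PCA component-score) and "Min-Input" (heart rate plus insulated
    scapula temperature) prediction equations with systematic offset
    correction, the full signal-conditioning chain (calibration, causal
    moving averages, zero-phase Butterworth low-pass filtering, heat-flux
    artifact removal, rectal lag alignment, complete-case masking),
    multivariate (Mahalanobis/chi-squared) and residual outlier
    screening, the model-development procedure (KMO and Bartlett
    adequacy statistics, PCA with varimax rotation and regression-method
    score coefficients, forced-entry and stepwise multiple linear
    regression, collinearity pruning, backward reduction), validation
    metrics (SEE, adjusted R-squared, mean offset), and a
    protocol-faithful synthetic heat-session simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
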