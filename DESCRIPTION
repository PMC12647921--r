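Package: picdf
Title: Paired Motor-Unit Estimates of Persistent Inward Current Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for decomposed high-density surface EMG motor-unit
    spike trains recorded during triangular isometric torque ramps. Computes
    smoothed discharge-rate curves by support vector regression, paired
    motor-unit delta frequency (dF, an index of persistent-inward-current
    mediated intrinsic motoneuron excitability), brace height (discharge
    nonlinearity), recruitment-threshold binning, and robust mixed-effects
    group and association statistics with cluster BCa bootstrap contrasts.
    Includes a motoneuron-pool simulator with injected, analytically known
    discharge hysteresis so every estimator can be validated against ground
    truth without raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    ggplot2,
    generics,
    e1071,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
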