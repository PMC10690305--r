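Package: backtraj
Title: Backward-Looking Biomarker Trajectories Before Life-Threatening
    Mass Effect in Large MCA Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how routinely collected laboratory values and
    vital signs evolve in the hours before life-threatening, space-occupying
    mass effect after large middle cerebral artery stroke.  Provides a seeded
    joint longitudinal-survival cohort simulator with exported ground truth,
    tidy cohort input/output with outcome adjudication (midline shift >= 5 mm,
    pineal gland shift > 4 mm, decompressive hemicraniectomy), flagging of
    erroneous electronic-health-record measurements, binning of irregular
    series to variable-specific grids with hourly interpolation,
    Aalen-Johansen cumulative incidence with death as a competing risk, and
    event-aligned backward-looking estimation of mean and quartile marker
    trajectories using inverse-probability-of-censoring weights.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
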