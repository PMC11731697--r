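Package: gaitfatigue
Title: Muscle Fatigue Detection from Wearable sEMG and Plantar Pressure
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies localized muscle fatigue from surface
    electromyography (sEMG) via the power-spectrum median frequency (MDF)
    and from insole plantar-pressure recordings via per-region peak
    pressures, with paired pre/post-fatigue statistics. Includes a
    zero-phase FIR bandpass filter, Welch and periodogram spectrum
    estimators, threshold-based gait step detection, a closed-form paired
    t-test, Borg RPE summaries, a synthetic-data generator that emulates
    band-limited sEMG with controllable spectral median and periodic gait
    pressure bursts with a forefoot-to-hindfoot fatigue redistribution,
    and a simulate/analyze/report command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
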