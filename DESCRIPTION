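Package: pausemark
Title: Speech-Pause Patterns and Alliance-Rupture Markers in Dyadic
    Psychotherapy Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects speech pauses in single-channel psychotherapy session
    recordings via amplitude-range histograms, attributes speech to patient
    or therapist with a supervised random-forest diariser, classifies every
    pause by its speaker-switching pattern (P_P, P_T, T_P, T_T), aggregates
    pauses into 10-second windows joined with alliance-rupture annotations,
    and analyses the pause-rupture association with linear mixed-effects
    models and a random-forest detector of the minimal-response rupture
    marker.  Ships a calibrated synthetic dyadic-session generator so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
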