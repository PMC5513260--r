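Package: lungedetect
Title: Automated Detection of Lunge-Feeding Events in Whale-Borne Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Threshold decision-tree detection of rorqual lunge-feeding events
    in multisensor bio-logging tag records. Derives band-limited flow noise,
    triaxial jerk and roll statistics from tag sensor streams, reduces them to
    one-second binned modes, and applies a hierarchy of peak, pairing and
    exclusion rules with separate shallow (<30 m) and deep branches. Includes
    an evaluation module that scores detections against manually audited lunge
    times with a 10 s tolerance and reproduces per-whale and cohort
    true-positive/false-positive statistics, plus a seeded synthetic tag-record
    generator with injected lunge signatures, dive profiles, fluking and
    surfacing artifacts so every detector stage is testable without tag
    deployments.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
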