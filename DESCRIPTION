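Package: usv44
Title: Classification and Sequence Analysis of Rat Ultrasonic Vocalizations
Version: 0.1.0
Authors@R:
    person("USV Analysis", "Contributors", email = "usv44@example.org",
           role = c("aut", "cre"))
Description: A pipeline for the analysis of rat ultrasonic vocalization (USV)
    recordings from aversive conditioning sessions. Implements rule-based call
    typing (long/short 22-kHz, 50-kHz, and long high-pitched "44-kHz" calls),
    contour element segmentation and subtype categorization, bout segmentation
    and call-type transition statistics, density-based (DBSCAN) and
    contour-based (k-means) repertoire clustering, motion-index freezing
    scoring with call-locked linkage, and a seeded synthetic session generator
    that emulates the statistical structure of fear-conditioning USV data so
    that every stage can be exercised without recorded audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
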