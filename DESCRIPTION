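Package: quartetpupil
Title: Pupillometry Pipeline for Mental Effort in Ensemble Music Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking per-bar musical and bodily predictors to pupil
    diameter in chamber-music performers and listeners. Implements a multi-step
    binocular pupillometry cleaning chain (outlier and blink-velocity gating,
    Savitzky-Golay smoothing, gap interpolation, baseline differencing),
    bar-timeline construction and per-bar aggregation, motion-capture quantity
    of motion, framed RMS sound level, spiral-array cloud diameter from spelled
    scores, and linear mixed-effects models with AR(1) serial correlation plus
    hierarchical chi-square/BIC model comparison. A seeded synthetic-data
    generator produces complete studies (scores, ratings, motion capture,
    audio, pupil traces) with known ground truth so every stage is verifiable
    without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmmTMB,
    jsonlite,
    signal,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
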