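Package: trackmetrics
Title: Behavioural Movement Metrics from GPS Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw 1 Hz GPS positioning logs into behavioural movement
    metrics for field experiments in the behavioural sciences. Reads GPX and
    logger CSV exports, applies movement quality control (unrealistic-speed
    masking, time-gap masking, dead-sensor exclusion), cuts continuous logs
    into analysis windows with geofence polygons and a finish line, and
    computes per participant and round the five movement variables speed,
    speed variability, intra-team distance, route deviation and
    route-deviation variability. Includes Tukey-fence outlier screening and a
    random-slopes linear mixed model linking the movement metrics to
    self-reported state scores, a seeded correlated-random-walk team
    simulator with known ground truth, offline track plotting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    callr,
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
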