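Package: drlmix
Title: Schedule Scoring and Temporal-Regulation Mixture Modelling of DRL
    Operant Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing response inhibition in operant sessions run
    under differential-reinforcement-of-low-rates (DRL) schedules.  Scores
    response streams under DRL, adjusting-DRL and progressive-ratio
    contingencies, models inter-response times as a shifted mixture of a
    gamma (timed) component and two exponential (burst and long-pause)
    components, fits the mixture per subject by maximum likelihood or by
    least squares on the binned cumulative distribution, and derives the
    standard response-inhibition indices (timed/burst/long proportions,
    response threshold, Weber fraction, burst decay rate).  Includes a
    synthetic-cohort generator emulating a chronic-intermittent-ethanol
    (CIE) vs control design, efficiency and stability statistics, effect
    sizes from t statistics, an exact two-sample Kolmogorov-Smirnov
    statistic for cumulative progressive-ratio curves, blood-ethanol
    utilities, and a delimited event-log format binding the stages into a
    reproducible simulate/fit/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
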