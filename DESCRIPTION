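Package: lostness
Title: Lostness Measures for Node-Based Navigation Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes navigational-efficiency ("lostness") statistics from
    timestamped event logs of players moving through a spatial node graph,
    as used in educational games and hypertext usability research. Provides
    a task-scoped global measure (an objectives-weighted mean of per-task
    lostness) and an objective-scoped local measure (the lostness formula
    applied to summed per-objective path counts), together with log
    validation and sessionization, a synthetic world/playthrough/cohort
    simulator with a planted lostness-knowledge effect, the standard
    validation statistics (descriptives, zero-order correlations,
    standardized multiple regression with collinearity and normality
    checks, paired comparisons, outlier screening), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
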