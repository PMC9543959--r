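Package: taskmod
Title: Task-Relevant Spatiotemporal Modules from Trial-Structured Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes trial-structured joint-angle time series into
    task-relevant spatial and temporal modules. A ridge regression estimates a
    relevance map linking standardized motion to a scalar per-trial performance
    measure; singular value decomposition of the map yields task-relevant
    modules and per-module predicted-performance fragments. The package also
    extracts conventional motion-relevant modules from reshaped SVDs, makes the
    analytical spectral identity between the two module families executable,
    provides the trial-to-trial adaptation statistics (perturbation-fragment
    correlations, phase-averaged module comparisons with ANOVA and Tukey tests),
    and generates synthetic low-rank smooth kinematic datasets with planted
    relevance maps, gain-perturbation schedules and simulated adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
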