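Package: mptflux
Title: Nighttime Eddy-Covariance CO2 Flux Filtering by the Modified Moving
    Point Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Filtering, gap-filling and partitioning of half-hourly
    eddy-covariance CO2 fluxes measured over hilly and complex terrain,
    where nighttime drainage flow biases the measured flux low even under
    turbulent conditions.  Implements the modified moving point test:
    per-period friction-velocity (u*) threshold detection by moving
    t-tests on temperature-normalized fluxes, a two-time-window split
    around the evening flux peak, a significance test for midnight CO2
    drainage, and combined filtering.  Includes Lloyd-Taylor
    temperature-response fitting with short-term temperature-sensitivity
    estimation and moving-window reference respiration, three baseline
    corrections (fixed u* filtering, light-response-curve intercept, and
    the sunset-peak van Gorsel variant), gap-filling of rejected
    nighttime fluxes, partitioning of net ecosystem exchange into gross
    primary productivity and ecosystem respiration with annual budgets,
    and a synthetic half-hourly flux generator with known truth for
    method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
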