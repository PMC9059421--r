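Package: relsurvuq
Title: Expected-Mortality Uncertainty in Relative Survival and Loss in
    Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether uncertainty in general-population
    (expected) mortality rates materially changes standard errors of
    relative survival and loss in life expectancy estimated from flexible
    parametric relative-survival models.  Provides stratified population
    life-table handling, Poisson spline smoothing of mortality rates,
    parametric-bootstrap replicate rate tables, a flexible parametric
    survival model on the log cumulative excess hazard scale with
    time-varying effects, conditional and marginal predictions of 5-year
    relative survival and loss in life expectancy with delta-method
    standard errors, Rubin's-rules pooling across replicate rate tables,
    and a synthetic-data generator emulating a national life table and a
    matched cancer cohort with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
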