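Package: strawsim
Title: Stochastic Simulation of Bee-Pollinated Strawberry Fruit Weight
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo simulator of strawberry fruit production driven by
    bee pollination: daily Poisson bee visits deposit pollen on a flower,
    age-dependent stigma receptivity and self-pollen compatibility thin the
    deposited grains to fertilized ovules (achenes) by binomial sampling, and
    achene count maps linearly to fruit weight with a Gaussian residual. The
    package runs flower cohorts, characterises the resulting fruit-weight
    distribution (adjusted Fisher-Pearson skewness with standard error and
    z score, one- and two-sample Kolmogorov-Smirnov tests, normal and
    three-parameter shifted-lognormal maximum-likelihood fits, Q-Q data),
    and sweeps visitation rate, self-compatibility and the seed-to-weight
    coefficient to quantify their effect on mean weight, marketable fraction
    and distribution skewness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
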