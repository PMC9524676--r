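Package: wormspan
Title: Hierarchical Process Models of Behavioral Aging and Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the timing of behavioral aging milestones
    (vigorous and weak movement cessation) relative to death in longitudinal
    cohorts such as C. elegans lifespan experiments. Provides stochastic
    first-passage-time simulators of one- and two-process Wiener decline
    models with gamma frailty and tunable inter-process coupling;
    nonparametric hazard estimation in chronological and clock-reset time;
    censored maximum-likelihood fits of Gompertz, Weibull, Weibull-gamma-
    frailty and Inverse-Gaussian hazard families; robust batch-adjusted
    regression relating movement-cessation times to lifespan with bootstrap
    inference and White heteroskedasticity tests; and accelerated
    failure time quantification of intervention effects, decomposed into
    proportional and disproportional components.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    lmtest,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
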