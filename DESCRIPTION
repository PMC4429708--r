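Package: adheretraj
Title: Adherence Trajectory Classes and the Impact of Adherence Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the level and the variability of adherence
    to antiretroviral therapy in longitudinal HIV cohorts. Implements
    12-month moving means and variances of monthly pill-count adherence, a
    rank-based normal-quantile standardization that decorrelates the moving
    variance from the moving mean, a latent-class trajectory model (a finite
    mixture of linear mixed models on a linear-spline time basis, fitted by
    EM) with maximum a posteriori classification, and the downstream
    association stages: a mixed logistic model for undetectable viral load,
    a mixed linear model for monthly CD4 change, and a time-dependent Cox
    model for mortality on monthly counting-process episodes. A synthetic
    cohort generator with known latent structure supports end-to-end
    parameter-recovery testing, and a pipeline orchestrator reproduces the
    full analysis from simulated or user-supplied data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    lme4,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
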