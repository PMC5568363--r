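Package: permtrial
Title: Randomization Inference and P-Value Error Bounds for Two-Arm Trials
Version: 0.1.0
Authors@R:
    person("permtrial", "maintainers", email = "maintainers@permtrial.org",
           role = c("aut", "cre"))
Description: Simulation and inference toolkit for quantifying how violations
    of the iid/normality assumptions behind clinical-trial statistics distort
    p-values and operating characteristics.  Populations are modelled as
    mixtures of latent response categories with optional within-cluster
    equicorrelation; trials support several randomization schemes and random
    sample-size regimes.  P-values are computed four ways (parametric normal
    tail, exact permutation, Monte-Carlo permutation, and the
    permutation-averaged parametric p-value), and Berry-Esseen machinery
    provides non-asymptotic uncertainty intervals for parametric p-values,
    guaranteed-decimal-digit and minimal-sample-size calculators, and
    Monte-Carlo Kolmogorov-Smirnov verification of the bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
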