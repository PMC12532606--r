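Package: msevo
Title: Latent-State Modelling of Multiple Sclerosis Disease Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a factor-analytic hidden Markov model to longitudinal
    multimodal multiple sclerosis data: a sparse probabilistic factor
    analysis with spike-and-slab (Laplace) priors and an Indian buffet
    process inclusion penalty reduces eight clinical and radiological
    features to a small number of interpretable composite dimensions;
    a hidden Markov model with multivariate normal emissions, estimated
    by multi-sequence Baum-Welch with BIC state selection, describes
    monthly transitions between disease states; transition-pattern
    analysis groups states into clinical meta-states (early/mild/evolving,
    asymptomatic radiological activity, relapse, advanced). Downstream
    analyses cover time to progression independent of relapse activity,
    continuous-time Markov treatment-effect estimation on panel-observed
    meta-state paths, and discrete-time prognostication of transition to
    advanced disease. A calibrated synthetic-cohort generator emulating
    the published transition structure makes the full pipeline testable
    without access to restricted trial databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    mgcv,
    survival,
    jsonlite,
    yaml,
    splines,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
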