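Package: bnstrength
Title: Significance Thresholds for Bootstrap Edge Confidences in Bayesian
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bootstrap model averaging for discrete Bayesian networks and a
    statistically motivated estimator of the confidence threshold that
    separates significant from non-significant edges.  Edge confidences
    (arc strengths) are obtained by learning a network structure on each of
    many nonparametric bootstrap replicates with score-based hill climbing
    under the Bayesian Dirichlet equivalent uniform (BDeu) score; the
    significance threshold is then estimated by minimising the L1 distance
    between the empirical cumulative distribution function of the observed
    confidences and the one-step CDF of their ideal, asymptotic
    configuration.  The package also provides forward sampling from discrete
    Bayesian networks, a generator of random benchmark-style networks, a
    plain-text network format, a permutation noise-floor baseline, and a
    structure-recovery evaluation harness (sensitivity, specificity,
    accuracy) comparing the estimated threshold with ad hoc ones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
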