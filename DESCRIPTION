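Package: iscn
Title: Individualized Structural Covariance Networks from Regional Cortical Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject (individualized) structural covariance networks
    from regional cortical thickness tables. Each subject's regional thickness
    profile is standardized within subject, z-scored against a normative
    control reference, and converted into a weighted 148x148 similarity matrix
    via an exponential kernel on pairwise deviation differences. The package
    computes weighted graph indices (strength, Onnela clustering coefficient,
    characteristic path length, global efficiency) at the global and nodal
    level, and provides the accompanying statistical stage: covariate-adjusted
    group comparison with false-discovery-rate control and LSD post-hoc tests,
    partial eta squared effect sizes, and bootstrap-supported partial Pearson
    correlations between network indices and clinical scores. A synthetic
    cohort generator with planted group effects makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    emmeans,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
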