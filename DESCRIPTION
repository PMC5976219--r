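Package: mrpipe
Title: Two-Sample Mendelian Randomization with Summary Statistics and
    Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization studies of the kind
    used to assess causal effects of cardiometabolic exposures on cerebrovascular
    outcomes: harmonization of GWAS summary statistics to a common effect allele
    (including strand resolution, palindromic-variant handling, LD-proxy
    substitution and LD clumping), the inverse-variance weighted, weighted
    median, penalized weighted median and MR-Egger estimators with heterogeneity
    and directional-pleiotropy diagnostics, an individual-level genetic risk
    score arm with covariate-adjusted and quartile-contrast models, a synthetic
    data generator with known causal ground truth for validating every pipeline
    stage, and a config-driven study driver with sensitivity re-runs and
    Bonferroni-adjusted significance flags.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'estimators.R'
    'grs.R'
    'harmonize.R'
    'mrpipe-package.R'
    'pipeline.R'
    'simulate.R'
    'summary-io.R'
    'utils.R'
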