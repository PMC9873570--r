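Package: medtraj
Title: Medication-Use Trajectory Phenotypes and Their Genetic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives lifelong medication-use phenotypes (purchase counts,
    medication switching, combination breadth, treatment discontinuation)
    from ATC-coded drug purchase registries, and analyses their genetic
    basis: covariate-adjusted association scans on inverse-normal
    transformed counts and binary patterns, locus definition, fixed-effect
    inverse-variance meta-analysis, approximate-Bayes-factor fine-mapping
    to purity-filtered 95 percent credible sets, Bayesian cross-trait
    model comparison against risk-factor and coronary-artery-disease
    summary statistics, and polygenic-score evaluation (quantile
    contrasts, Nagelkerke pseudo-R2, Davidson-MacKinnon J-test, repeated
    train/validation AUC). Includes a synthetic registry and genotype
    generator with known truth so every stage is testable without access
    to restricted registry or biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
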