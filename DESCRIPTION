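Package: methrisk
Title: Prospective Epigenome-Wide Association, Methylation Risk Scores and
    Epigenetic Mediation for Longitudinal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prospective epigenome-wide association analyses of
    Illumina 450k-style beta values against a latent substance-use liability
    factor: maximum-likelihood confirmatory factor analysis (first- and
    second-order) with ML fit indices, reference-based cell-composition
    estimation by constrained projection, probe-wise covariate-adjusted
    regression with Benjamini-Hochberg false discovery control,
    spatially-correlated p-value region calling (Stouffer-Liptak-Kechris
    smoothing with Sidak correction), temporal follow-forward and
    autocorrelation analyses, weighted cumulative DNA-methylation risk
    scores with mQTL-excluded variants, and bootstrapped path-analytic
    mediation of prenatal exposures. Includes a seeded two-timepoint
    synthetic cohort generator with planted ground truth so the full
    pipeline is testable without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
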