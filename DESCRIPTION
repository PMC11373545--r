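Package: protmr
Title: Proteomics-Driven Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline from a serum protein-array screen to causal
    inference on disease risk. Provides a differential-expression screen for
    protein arrays (plain and empirical-Bayes moderated tests), genetic
    instrument selection from pQTL summary statistics (F-statistic and
    minor-allele-frequency filters, local LD pruning, proxy lookup), allele
    harmonization of exposure and outcome summary statistics, a full
    two-sample Mendelian randomization estimator suite (Wald ratio,
    fixed/random-effects inverse-variance weighting, MR-Egger, weighted
    median, weighted mode) with heterogeneity statistics and
    Benjamini-Hochberg correction, sensitivity analyses (leave-one-out,
    MR-PRESSO global/outlier/distortion tests, funnel data, Egger-intercept
    pleiotropy test), network-MR mediation with proportion mediated, analytic
    power for binary outcomes, and a synthetic-data module that generates
    summary statistics, mediation trios and expression matrices with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
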