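Package: mrpipe
Title: Two-Sample Mendelian Randomization for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("mrpipe", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable two-sample Mendelian randomization (MR)
    pipeline for GWAS summary statistics: instrument selection (p-value
    filter, LD clumping, confounder exclusion list, F-statistic screen),
    exposure/outcome harmonization with palindromic-SNP resolution,
    inverse-variance-weighted, MR-Egger and weighted-median causal
    estimators with odds-ratio reporting, sensitivity diagnostics
    (Cochran's Q, Egger intercept, leave-one-out, MR-PRESSO), forward and
    reverse batch orchestration, and a synthetic summary-statistics
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
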