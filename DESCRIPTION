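Package: smrprs
Title: Functional Polygenic Risk Scores from Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putatively functional disease risk variants by
    integrating GWAS summary statistics with expression and methylation
    quantitative trait locus (eQTL/mQTL) summary data through summary-data
    Mendelian randomization (SMR) with the heterogeneity-in-dependent-
    instruments (HEIDI) filter, builds polygenic risk scores (PRS) from the
    nominated variants with plink-style scoresum semantics, and benchmarks
    them against established GWAS-derived scores using AUC, odds ratio per
    standard deviation, Youden operating points, centile-based high-risk
    classification, high-risk overlap, and variant-subsampling analyses.
    Ships simulation generators for LD-structured reference panels,
    molecular-trait and case-control GWAS summary statistics under
    pleiotropy, linkage, and null architectures, and individual-level
    cohorts with known ground truth, so the full pipeline is testable
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pROC,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
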