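Package: smrpipe
Title: Summary-Data Mendelian Randomization for GWAS-eQTL Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates GWAS and eQTL summary statistics to estimate the
    effect of gene expression on a complex trait by summary-data Mendelian
    randomization (SMR). Implements the single-instrument Wald ratio
    b_xy = b_zy / b_zx with a delta-method standard error and a one
    degree-of-freedom chi-square test, together with allele harmonization
    of summary statistics, cis-eQTL instrument selection, multiple-testing
    policies, and cross-experiment aggregation of significant SNPs and
    genes. A seeded generator simulates individual-level cohorts under
    known causal structure and reduces them to summary statistics, so the
    whole pipeline is testable without external consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
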