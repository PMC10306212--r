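Package: rvburden
Title: Rare-Variant Burden Testing Against Public Control Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene- and pathway-level burden tests of qualifying rare
    deleterious variants in a small jointly-called case cohort against
    allele-count summary statistics from large public control databases
    (gnomAD/ExAC style). Implements coverage harmonization between case and
    control sequencing, qualifying-variant filtration (CADD and predicted
    loss-of-function consequences with allele-frequency thresholds and
    source fallback), dominant-model carrier counting with a two-sided
    Fisher's exact collapsing test, gene-set aggregation from GMT files,
    quantile-window genomic inflation factor estimation with multiplicative
    p-value correction, and Bonferroni multiplicity control. Includes a
    synthetic-data generator that emulates the full input bundle (multi-sample
    VCF, control summary tables, coverage tracks, annotations, gene sets)
    with known ground truth for end-to-end statistical validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
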