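Package: hijackr
Title: Detection of Enhancer Hijacking Events from Cohort WGS and RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative enhancer-hijacking events in individual cancer
    samples from cohort-level structural-variant breakends, copy-number
    segments, gene expression (TPM) and allele-specific read counts. For each
    expressed gene, samples with a breakpoint in the gene's (extended)
    topologically associating domain are scored against breakpoint-free
    reference samples by combining a copy-number-corrected overexpression
    score, a beta-binomial allele-specific expression score, a rank-weighted
    hijacked-enhancer score and a deletion penalty. Gene-level scores are
    converted to empirical p-values against a resampled null and adjusted by
    Benjamini-Hochberg. Includes a synthetic-cohort simulator with injected
    ground-truth events for end-to-end benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
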