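Package: crisprares
Title: Pooled CRISPR Activation Resistance-Screen Analysis and Combination
    Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of pooled CRISPR activation (CRISPRa) drug-resistance
    screens: exact-match guide quantification from single-end FASTQ reads,
    replicate averaging and total-count normalization, fold-enrichment hit
    calling with a multi-guide gene rule and dual-drug candidate
    intersection, and per-gene significance testing.  Companion pharmacology
    utilities cover four-parameter logistic dose-response fitting with EDx
    estimation, Bliss-independence combination indices (fixed pairs, dose
    matrices and apoptosis endpoints), delta-delta-Ct relative
    quantification and ellipsoid tumor volumes.  An expression-cutoff
    survival scan couples Kaplan-Meier estimation and log-rank testing with
    Bonferroni correction over the tested cutoffs.  Seeded synthetic
    generators emulate the pooled-screen selection dynamics, sequencing
    reads, viability plates, synergy matrices and survival cohorts that the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    survival,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
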