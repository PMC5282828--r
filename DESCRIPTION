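Package: lofprio
Title: Recessive Loss-of-Function Variant Filtering and Functional
    Prioritization of Disease Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discovering and prioritizing
    candidate disease genes from case/control exome cohorts under a
    recessive inheritance model. Implements loss-of-function variant
    classification (stop-affecting variants, immediate-stop frameshifts,
    near-junction splice variants), a multi-database minor allele
    frequency filter cascade with homozygous and compound-heterozygous
    candidate detection, gene-level rare-variant burden and
    variance-component tests calibrated by phenotype permutation,
    high-content RNAi screen statistics (robust SSMD, robust Z'-factor,
    plate normalization, two-clone hit calling), scoring of Drosophila
    alpha-synuclein enhancer screens and C. elegans viability/motility
    assays, cross-cohort enrichment and tolerability arithmetic,
    replication matching, and integration of functional and genetic
    evidence into a prioritized gene set. A synthetic-data module
    generates exome cohorts with planted recessive genotypes and screen
    plates with planted effects so every step can be tested against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    jsonlite
Config/testthat/edition: 3
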