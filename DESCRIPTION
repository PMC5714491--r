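Package: bsaMap
Title: Bulk Segregant Mapping of EMS Mutants with Variant, MS and qPCR Utilities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identification of causal genes from chemically mutagenized plant
    lines by pooled-segregant (bulk segregant) sequencing. Provides a
    synthetic-data generator for F2 cohorts and pooled SNP profiles with
    realistic artifact structure; the candidate-identification pipeline
    (allele-frequency filter, read-depth filter, sequential subtraction of
    sibling mutant SNP profiles) with a per-stage audit trail; variant-effect
    classification against a reference genome and gene models, including an
    exact-match RNAi off-target scan; molecular-formula arithmetic for
    negative-mode tandem-MS annotation of flavonoids (deprotonated ions,
    glycosyl neutral losses, retro-Diels-Alder C-ring fragments); and
    efficiency-corrected qRT-PCR quantification with Mendelian segregation
    goodness-of-fit tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Genetics, VariantAnnotation, Sequencing, MassSpectrometry, qPCR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
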