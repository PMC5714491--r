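#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
NULL

.PHENOTYPE_LEVELS <- c("light", "dark", "very_pale")

#' Reference genome with gene models and repeat annotation
#'
#' A `GenomeModel` bundles the three pieces of reference information the
#' mapping pipeline needs: chromosome sequences, protein-coding gene models
#' (as CDS intervals), and intervals flagged as repetitive.  It stands in for
#' a draft genome assembly plus its annotation.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of chromosome sequences;
#'   names are the chromosome names and must be unique.
#' @slot genes A [GenomicRanges::GRanges] of CDS intervals with metadata
#'   columns `gene_id` (character), `exon_rank` (integer, 1-based in genomic
#'   order) and `is_causal` (logical).  Intervals of one gene must be
#'   non-overlapping and lie on one chromosome and strand; the summed CDS
#'   length of each gene must be divisible by 3.
#' @slot repeats A [GenomicRanges::GRanges] of intervals flagged repetitive.
#'
#' @seealso [genomeModel()] for the validated constructor,
#'   [simulateGenome()] to generate one.
#' @exportClass GenomeModel
setClass("GenomeModel", representation(
    sequences = "DNAStringSet",
    genes     = "GRanges",
    repeats   = "GRanges"
))

setValidity("GenomeModel", function(object) {
    msg <- character(0)
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "chromosome names must be present and unique")
    g <- object@genes
    if (length(g)) {
        need <- c("gene_id", "is_causal")
        if (!all(need %in% colnames(mcols(g))))
            msg <- c(msg, "genes must carry mcols 'gene_id' and 'is_causal'")
        else {
            bad <- !(as.character(seqnames(g)) %in% nm)
            if (any(bad))
                msg <- c(msg, "gene CDS on unknown chromosome")
            else {
                lens <- width(object@sequences)[match(as.character(seqnames(g)), nm)]
                if (any(start(g) < 1L) || any(end(g) > lens))
                    msg <- c(msg, "gene CDS intervals exceed chromosome bounds")
            }
            cdslen <- tapply(width(g), mcols(g)$gene_id, sum)
            if (any(cdslen %% 3L != 0L))
                msg <- c(msg, "total CDS length of each gene must be divisible by 3")
            for (gid in unique(mcols(g)$gene_id)) {
                gg <- g[mcols(g)$gene_id == gid]
                if (length(unique(as.character(strand(gg)))) != 1L ||
                    length(unique(as.character(seqnames(gg)))) != 1L)
                    msg <- c(msg, sprintf("gene '%s' spans strands or chromosomes", gid))
                o <- order(start(gg))
                if (length(gg) > 1L && any(start(gg)[o][-1L] <= end(gg)[o][-length(gg)]))
                    msg <- c(msg, sprintf("gene '%s' has overlapping CDS intervals", gid))
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' A mutagenized line and its induced point mutations
#'
#' Represents one chemically mutagenized line: the set of induced SNPs
#' (relative to the reference) and, among them, the single causal lesion,
#' which by construction is a nonsynonymous change in the causal gene.
#'
#' @slot lineId Single character identifier of the line.
#' @slot snps A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `causal` (logical; exactly one `TRUE`).
#'
#' @seealso [simulateMutantLine()]
#' @exportClass MutantLine
setClass("MutantLine", representation(
    lineId = "character",
    snps   = "data.frame"
))

setValidity("MutantLine", function(object) {
    msg <- character(0)
    if (length(object@lineId) != 1L)
        msg <- c(msg, "lineId must be a single string")
    s <- object@snps
    need <- c("chrom", "pos", "ref", "alt", "causal")
    if (!all(need %in% names(s)))
        msg <- c(msg, "snps must have columns chrom, pos, ref, alt, causal")
    else {
        if (sum(s$causal) != 1L)
            msg <- c(msg, "exactly one SNP must be flagged causal")
        if (anyDuplicated(paste(s$chrom, s$pos)))
            msg <- c(msg, "induced SNP positions must be unique within the line")
        if (any(s$ref == s$alt))
            msg <- c(msg, "ref and alt alleles must differ")
    }
    if (length(msg)) msg else TRUE
})

#' An F2 cohort segregating at a single causal locus
#'
#' Holds, for each F2 individual, the mutant-allele dosage at the causal
#' locus (0, 1 or 2), the dosage at each simulated marker SNP, and the
#' phenotype class implied by the causal genotype (`light` for +/+, `dark`
#' for +/-, `very_pale` for -/-; the heterozygote is the darkest class, the
#' overdominant pattern this design emulates).
#'
#' @slot genotypes Integer vector, mutant-allele dosage at the causal locus.
#' @slot phenotypes Factor with levels `light`, `dark`, `very_pale`.
#' @slot markerDosage Integer matrix (individuals x markers) of mutant-allele
#'   dosages at the line's non-causal SNPs.
#' @slot markerInfo `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `r` (recombination fraction with the causal locus).
#'
#' @seealso [simulateF2()], [poolAndSequence()]
#' @exportClass F2Cohort
setClass("F2Cohort", representation(
    genotypes    = "integer",
    phenotypes   = "factor",
    markerDosage = "matrix",
    markerInfo   = "data.frame"
))

setValidity("F2Cohort", function(object) {
    msg <- character(0)
    n <- length(object@genotypes)
    if (!all(object@genotypes %in% 0:2))
        msg <- c(msg, "genotypes must be dosages 0, 1 or 2")
    if (length(object@phenotypes) != n)
        msg <- c(msg, "phenotypes and genotypes lengths differ")
    if (!identical(levels(object@phenotypes), .PHENOTYPE_LEVELS))
        msg <- c(msg, "phenotype levels must be light, dark, very_pale")
    expected <- factor(.PHENOTYPE_LEVELS[object@genotypes + 1L],
                       levels = .PHENOTYPE_LEVELS)
    if (!identical(as.character(expected), as.character(object@phenotypes)))
        msg <- c(msg, "phenotype must be the deterministic map of causal dosage")
    if (nrow(object@markerDosage) != n)
        msg <- c(msg, "markerDosage must have one row per individual")
    if (ncol(object@markerDosage) != nrow(object@markerInfo))
        msg <- c(msg, "markerDosage columns must match markerInfo rows")
    if (length(msg)) msg else TRUE
})

#' Per-line SNP profile from pooled sequencing
#'
#' The substrate of the filtering pipeline: one variant call set for one
#' line, with per-site alternate-read counts, total depth and alternate
#' allele frequency.
#'
#' @slot lineId Single character identifier of the line.
#' @slot records `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `alt_count`, `depth`, `frequency`.  Keys
#'   (`chrom`,`pos`,`ref`,`alt`) are unique; `0 <= alt_count <= depth`; and
#'   `frequency` equals `alt_count/depth` to within rounding.
#'
#' @seealso [snpProfile()], [readSnpVcf()], [poolAndSequence()]
#' @exportClass SnpProfile
setClass("SnpProfile", representation(
    lineId  = "character",
    records = "data.frame"
))

setValidity("SnpProfile", function(object) {
    msg <- character(0)
    if (length(object@lineId) != 1L)
        msg <- c(msg, "lineId must be a single string")
    r <- object@records
    need <- c("chrom", "pos", "ref", "alt", "alt_count", "depth", "frequency")
    if (!all(need %in% names(r)))
        msg <- c(msg, paste("records must have columns", paste(need, collapse = ", ")))
    else if (nrow(r)) {
        if (any(r$depth <= 0L))
            msg <- c(msg, "records with zero depth are not representable")
        if (any(r$alt_count < 0L) || any(r$alt_count > r$depth))
            msg <- c(msg, "alt_count must lie in [0, depth]")
        if (any(abs(r$frequency - r$alt_count / r$depth) > 1e-6))
            msg <- c(msg, "frequency must equal alt_count/depth within rounding")
        if (anyDuplicated(paste(r$chrom, r$pos, r$ref, r$alt)))
            msg <- c(msg, "duplicate (chrom, pos, ref, alt) keys in profile")
    }
    if (length(msg)) msg else TRUE
})

#' Filtering configuration for the candidate-identification pipeline
#'
#' @slot minFrequency Alternate-allele frequency cutoff; records with
#'   frequency strictly greater are retained (the ">95 percent" rule).
#' @slot maxDepth Depth cutoff; records with depth strictly greater are
#'   discarded as likely repetitive/collapsed regions (kept at exactly the
#'   cutoff).
#' @slot matchMode Either `"position_and_allele"` (default) or
#'   `"position_only"`: how records are matched during profile subtraction.
#'
#' @seealso [filterConfig()]
#' @exportClass FilterConfig
setClass("FilterConfig", representation(
    minFrequency = "numeric",
    maxDepth     = "numeric",
    matchMode    = "character"
))

setValidity("FilterConfig", function(object) {
    msg <- character(0)
    if (length(object@minFrequency) != 1L || is.na(object@minFrequency) ||
        object@minFrequency <= 0 || object@minFrequency >= 1)
        msg <- c(msg, "minFrequency must lie strictly inside (0, 1)")
    if (length(object@maxDepth) != 1L || is.na(object@maxDepth) ||
        object@maxDepth <= 0)
        msg <- c(msg, "maxDepth must be positive")
    if (!object@matchMode %in% c("position_and_allele", "position_only"))
        msg <- c(msg, "matchMode must be 'position_and_allele' or 'position_only'")
    if (length(msg)) msg else TRUE
})

#' Audit-trailed result of the candidate-identification pipeline
#'
#' Records the number of SNPs surviving each pipeline stage (raw, frequency
#' filter, depth filter, one per subtracted sibling profile) and the final
#' candidate list, optionally annotated with variant effects and ranked.
#'
#' @slot focalLine Identifier of the focal mutant line.
#' @slot stageCounts `data.frame` with columns `stage` and `count`; counts
#'   are monotonically non-increasing.
#' @slot candidates `data.frame` of surviving records, with effect columns
#'   (`category`, `aa_change`, `conservation`, `in_repeat`, `rank`) when the
#'   pipeline was run with a genome.
#'
#' @exportClass CandidateReport
setClass("CandidateReport", representation(
    focalLine   = "character",
    stageCounts = "data.frame",
    candidates  = "data.frame"
))

setValidity("CandidateReport", function(object) {
    msg <- character(0)
    sc <- object@stageCounts
    if (!all(c("stage", "count") %in% names(sc)))
        msg <- c(msg, "stageCounts must have columns stage and count")
    else if (nrow(sc) > 1L && any(diff(sc$count) > 0))
        msg <- c(msg, "stage counts must be monotonically non-increasing")
    if (length(msg)) msg else TRUE
})

#' Simulation parameters for the synthetic study design
#'
#' One object holding every tunable of the generator, so that a fixed
#' parameter set plus seed reproduces the whole synthetic study
#' bit-for-bit.  Defaults mirror the mapping design the pipeline was built
#' for: an F2 of 455 individuals, a pool of 96 phenotype-selected
#' homozygotes, mean coverage 100x.
#'
#' @slot genomeLength Total genome size in bp.
#' @slot nChromosomes Number of chromosomes (equal sizes).
#' @slot nGenes Number of simulated protein-coding genes.
#' @slot cdsLength Total CDS length per gene in bp (split over two exons).
#' @slot nRepeats,repeatLength Number and length of repeat-flagged intervals.
#' @slot nInducedSnps Induced point mutations per mutagenized line.
#' @slot emsTransitionFraction Fraction of induced SNPs forced to the
#'   G:C->A:T transitions characteristic of EMS mutagenesis.
#' @slot nF2 F2 cohort size.
#' @slot cmPerMb Genetic-map density used to derive same-chromosome
#'   recombination fractions (Haldane, no interference).
#' @slot poolSize Number of phenotype-selected individuals pooled.
#' @slot meanDepth,depthDispersion Negative-binomial sequencing depth model
#'   (mean and `size` parameter).
#' @slot baseErrorRate Per-read symmetric allele-flip probability.
#' @slot nArtifactSnps Artifactual SNPs shared across all line profiles.
#' @slot artifactFrequencyRange Frequency interval of artifact SNPs.
#' @slot artifactHighdepthFraction Fraction of artifacts given depth above
#'   the default depth-filter cutoff (collapsed-repeat analogs).
#' @slot seed Integer RNG seed; fixed seed implies bit-identical output.
#'
#' @seealso [simParams()]
#' @exportClass SimParams
setClass("SimParams", representation(
    genomeLength = "numeric",
    nChromosomes = "numeric",
    nGenes       = "numeric",
    cdsLength    = "numeric",
    nRepeats     = "numeric",
    repeatLength = "numeric",
    nInducedSnps = "numeric",
    emsTransitionFraction = "numeric",
    nF2          = "numeric",
    cmPerMb      = "numeric",
    poolSize     = "numeric",
    meanDepth    = "numeric",
    depthDispersion = "numeric",
    baseErrorRate   = "numeric",
    nArtifactSnps   = "numeric",
    artifactFrequencyRange    = "numeric",
    artifactHighdepthFraction = "numeric",
    seed         = "numeric"
))

setValidity("SimParams", function(object) {
    msg <- character(0)
    chk1 <- function(x, nm, min = NULL) {
        if (length(slot(object, x)) != 1L || is.na(slot(object, x)))
            return(sprintf("'%s' must be a single non-missing number", nm))
        if (!is.null(min) && slot(object, x) < min)
            return(sprintf("'%s' must be >= %s", nm, min))
        NULL
    }
    for (f in c("genomeLength", "nChromosomes", "nGenes", "cdsLength",
                "nRepeats", "repeatLength", "nInducedSnps", "nF2",
                "poolSize", "meanDepth", "depthDispersion", "nArtifactSnps",
                "seed"))
        msg <- c(msg, chk1(f, f, min = 0))
    for (f in c("emsTransitionFraction", "baseErrorRate")) {
        v <- slot(object, f)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", f))
    }
    if (length(object@cmPerMb) != 1L || object@cmPerMb < 0)
        msg <- c(msg, "'cmPerMb' must be a single non-negative number")
    fr <- object@artifactFrequencyRange
    if (length(fr) != 2L || any(is.na(fr)) || fr[1] > fr[2] ||
        fr[1] < 0 || fr[2] > 1)
        msg <- c(msg, "'artifactFrequencyRange' must be an interval within [0, 1]")
    hv <- object@artifactHighdepthFraction
    if (length(hv) != 1L || is.na(hv) || hv < 0 || hv > 1)
        msg <- c(msg, "'artifactHighdepthFraction' must be a probability in [0, 1]")
    if (object@cdsLength %% 3 != 0)
        msg <- c(msg, "'cdsLength' must be divisible by 3")
    if (length(msg)) msg else TRUE
})

#' Elemental formula for mass-spectrometric arithmetic
#'
#' Integer element counts (C, H, O, N, S, P supported) plus a provenance
#' label, used for nominal/monoisotopic masses, deprotonated ions, neutral
#' losses and retro-Diels-Alder fragment bookkeeping.
#'
#' @slot counts Named integer vector of element counts, all non-negative,
#'   at least one atom.
#' @slot label Free-text provenance label (e.g. a compound name).
#'
#' @seealso [parseFormula()], [nominalMass()], [deprotonatedMz()]
#' @exportClass MolecularFormula
setClass("MolecularFormula", representation(
    counts = "integer",
    label  = "character"
))

setValidity("MolecularFormula", function(object) {
    msg <- character(0)
    cnt <- object@counts
    if (is.null(names(cnt)) || any(names(cnt) == ""))
        msg <- c(msg, "element counts must be named")
    if (any(cnt < 0L))
        msg <- c(msg, "element counts must be non-negative")
    if (sum(cnt) < 1L)
        msg <- c(msg, "formula must contain at least one atom")
    unknown <- setdiff(names(cnt), names(.NOMINAL_MASS))
    if (length(unknown))
        msg <- c(msg, paste("unknown element symbol:", paste(unknown, collapse = ", ")))
    if (length(msg)) msg else TRUE
})
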