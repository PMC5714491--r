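#' @describeIn SnpProfile-class Line identifier.
#' @export
setMethod("lineId", "SnpProfile", function(x) x@lineId)

#' @describeIn MutantLine-class Line identifier.
#' @export
setMethod("lineId", "MutantLine", function(x) x@lineId)

#' @describeIn SnpProfile-class Record table
#'   (`chrom`, `pos`, `ref`, `alt`, `alt_count`, `depth`, `frequency`).
#' @export
setMethod("records", "SnpProfile", function(x) x@records)

#' @describeIn GenomeModel-class Chromosome sequences as a `DNAStringSet`.
#' @export
setMethod("chromSequences", "GenomeModel", function(x) x@sequences)

#' @describeIn GenomeModel-class CDS intervals as a `GRanges` with
#'   `gene_id`, `exon_rank` and `is_causal` metadata columns.
#' @export
setMethod("geneRanges", "GenomeModel", function(x) x@genes)

#' @describeIn GenomeModel-class Repeat-flagged intervals as a `GRanges`.
#' @export
setMethod("repeatRanges", "GenomeModel", function(x) x@repeats)

#' @describeIn MutantLine-class All induced SNPs as a `data.frame`.
#' @export
setMethod("inducedSnps", "MutantLine", function(x) x@snps)

#' @describeIn MutantLine-class The single causal SNP (one-row `data.frame`).
#' @export
setMethod("causalSnp", "MutantLine", function(x) x@snps[x@snps$causal, , drop = FALSE])

#' @describeIn F2Cohort-class Mutant-allele dosage at the causal locus.
#' @export
setMethod("causalGenotypes", "F2Cohort", function(x) x@genotypes)

#' @describeIn F2Cohort-class Phenotype classes.
#' @export
setMethod("phenotypes", "F2Cohort", function(x) x@phenotypes)

#' @describeIn F2Cohort-class Marker dosage matrix (individuals x markers).
#' @export
setMethod("markerDosage", "F2Cohort", function(x) x@markerDosage)

#' @describeIn F2Cohort-class Marker table with recombination fractions.
#' @export
setMethod("markerInfo", "F2Cohort", function(x) x@markerInfo)

#' @describeIn CandidateReport-class Line the report was computed for.
#' @export
setMethod("lineId", "CandidateReport", function(x) x@focalLine)

#' @describeIn CandidateReport-class Per-stage surviving SNP counts.
#' @export
setMethod("stageCounts", "CandidateReport", function(x) x@stageCounts)

#' @describeIn CandidateReport-class Final candidate table.
#' @export
setMethod("candidates", "CandidateReport", function(x) x@candidates)

#' Construct a SNP profile
#'
#' @param lineId Single character line identifier.
#' @param records `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, and optionally `frequency` (recomputed from the
#'   counts when absent).
#' @return A validated [SnpProfile].
#' @export
snpProfile <- function(lineId, records) {
    if (is.null(records$frequency) && !is.null(records$alt_count))
        records$frequency <- records$alt_count / records$depth
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    rownames(records) <- NULL
    new("SnpProfile", lineId = as.character(lineId), records = records)
}

#' Construct a genome model
#'
#' @param sequences Named [Biostrings::DNAStringSet] of chromosomes.
#' @param genes `GRanges` of CDS intervals with `gene_id`, `exon_rank`,
#'   `is_causal` metadata columns.
#' @param repeats `GRanges` of repeat-flagged intervals.
#' @return A validated [GenomeModel].
#' @export
genomeModel <- function(sequences, genes = GRanges(), repeats = GRanges()) {
    new("GenomeModel", sequences = sequences, genes = genes, repeats = repeats)
}

#' Construct a filtering configuration
#'
#' @param minFrequency Frequency cutoff (strictly-greater retained);
#'   default 0.95.
#' @param maxDepth Depth cutoff (strictly-greater discarded); default 200.
#' @param matchMode `"position_and_allele"` (default) or `"position_only"`.
#' @return A validated [FilterConfig].
#' @export
filterConfig <- function(minFrequency = 0.95, maxDepth = 200,
                         matchMode = c("position_and_allele", "position_only")) {
    matchMode <- match.arg(matchMode)
    new("FilterConfig", minFrequency = minFrequency, maxDepth = maxDepth,
        matchMode = matchMode)
}

setMethod("show", "GenomeModel", function(object) {
    cat(sprintf("GenomeModel: %d chromosome(s), %s bp total\n",
                length(object@sequences),
                format(sum(width(object@sequences)), big.mark = ",")))
    cat(sprintf("  %d gene(s) (%d CDS segments), %d repeat interval(s)\n",
                length(unique(mcols(object@genes)$gene_id)),
                length(object@genes), length(object@repeats)))
})

setMethod("show", "MutantLine", function(object) {
    cs <- causalSnp(object)
    cat(sprintf("MutantLine '%s': %d induced SNP(s)\n",
                object@lineId, nrow(object@snps)))
    cat(sprintf("  causal: %s:%d %s>%s\n", cs$chrom, cs$pos, cs$ref, cs$alt))
})

setMethod("show", "F2Cohort", function(object) {
    tab <- table(object@phenotypes)
    cat(sprintf("F2Cohort: %d individuals (%s), %d marker(s)\n",
                length(object@genotypes),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
                ncol(object@markerDosage)))
})

setMethod("show", "SnpProfile", function(object) {
    cat(sprintf("SnpProfile '%s': %d record(s)\n",
                object@lineId, nrow(object@records)))
    if (nrow(object@records))
        print(utils::head(object@records, 3L))
})

setMethod("show", "FilterConfig", function(object) {
    cat(sprintf(
        "FilterConfig: keep frequency > %g, depth <= %g; match by %s\n",
        object@minFrequency, object@maxDepth, object@matchMode))
})

setMethod("show", "CandidateReport", function(object) {
    cat(sprintf("CandidateReport for line '%s'\n", object@focalLine))
    cat("  stages:\n")
    for (i in seq_len(nrow(object@stageCounts)))
        cat(sprintf("    %-28s %d\n", object@stageCounts$stage[i],
                    object@stageCounts$count[i]))
    cat(sprintf("  %d candidate(s)\n", nrow(object@candidates)))
})

setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        "SimParams: genome %g bp / %g chr, %g genes; %g SNPs/line (EMS %.2f)\n",
        object@genomeLength, object@nChromosomes, object@nGenes,
        object@nInducedSnps, object@emsTransitionFraction))
    cat(sprintf(
        "  F2 n=%g, pool=%g, depth NB(mean=%g, size=%g), error=%g, seed=%g\n",
        object@nF2, object@poolSize, object@meanDepth,
        object@depthDispersion, object@baseErrorRate, object@seed))
})

setMethod("show", "MolecularFormula", function(object) {
    cat(sprintf("MolecularFormula %s (%s): nominal mass %d Da\n",
                formulaString(object),
                if (length(object@label)) object@label else "unlabelled",
                nominalMass(object)))
})
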