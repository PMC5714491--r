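#' @rdname SnpProfile-class
#' @param object,x An object.
#' @export
setGeneric("lineId", function(x) standardGeneric("lineId"))

#' @rdname SnpProfile-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname GenomeModel-class
#' @export
setGeneric("chromSequences", function(x) standardGeneric("chromSequences"))

#' @rdname GenomeModel-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GenomeModel-class
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))

#' @rdname MutantLine-class
#' @export
setGeneric("inducedSnps", function(x) standardGeneric("inducedSnps"))

#' @rdname MutantLine-class
#' @export
setGeneric("causalSnp", function(x) standardGeneric("causalSnp"))

#' @rdname F2Cohort-class
#' @export
setGeneric("causalGenotypes", function(x) standardGeneric("causalGenotypes"))

#' @rdname F2Cohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname F2Cohort-class
#' @export
setGeneric("markerDosage", function(x) standardGeneric("markerDosage"))

#' @rdname F2Cohort-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname CandidateReport-class
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname CandidateReport-class
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' Filter a SNP profile by alternate-allele frequency
#'
#' Retains exactly the records whose alternate-allele frequency is strictly
#' greater than `minFrequency`.  In a pool of phenotype-selected causal-locus
#' homozygotes the causal allele is present on every chromosome, so its
#' observed frequency is near 1; unlinked heterozygous sites sit near 0.5
#' and are removed.  The strict inequality implements the ">95 percent"
#' reading of the cutoff.
#'
#' @param profile A [SnpProfile].
#' @param minFrequency Cutoff in (0, 1); default 0.95.
#' @return A new [SnpProfile]; the input is unmodified.
#' @examples
#' prof <- snpProfile("m1", data.frame(chrom = "chr1", pos = c(10L, 20L),
#'     ref = "G", alt = "A", alt_count = c(94L, 99L), depth = 100L,
#'     frequency = c(0.94, 0.99)))
#' nrow(records(filterByFrequency(prof, 0.95)))
#' @export
setGeneric("filterByFrequency",
    function(profile, minFrequency = 0.95) standardGeneric("filterByFrequency"))

#' Filter a SNP profile by depth of coverage
#'
#' Discards records whose depth exceeds `maxDepth`; records at exactly the
#' cutoff are kept.  Excessive coverage marks regions where reads from
#' collapsed repeats or mis-assembled copies pile up, producing artifactual
#' high-frequency calls.
#'
#' @param profile A [SnpProfile].
#' @param maxDepth Positive depth cutoff; default 200.
#' @return A new [SnpProfile]; the input is unmodified.
#' @export
setGeneric("filterByDepth",
    function(profile, maxDepth = 200) standardGeneric("filterByDepth"))
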