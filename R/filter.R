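.recordKeys <- function(rec, matchMode) {
    if (matchMode == "position_only")
        paste(rec$chrom, rec$pos)
    else
        paste(rec$chrom, rec$pos, rec$ref, rec$alt)
}

#' @describeIn filterByFrequency Method for [SnpProfile].
#' @export
setMethod("filterByFrequency", "SnpProfile",
    function(profile, minFrequency = 0.95) {
        if (!is.numeric(minFrequency) || length(minFrequency) != 1L ||
            is.na(minFrequency) || minFrequency <= 0 || minFrequency >= 1)
            stop("config error: 'minFrequency' must lie strictly inside (0, 1)")
        rec <- records(profile)
        snpProfile(lineId(profile),
                   rec[rec$frequency > minFrequency, , drop = FALSE])
    })

#' @describeIn filterByDepth Method for [SnpProfile].
#' @export
setMethod("filterByDepth", "SnpProfile",
    function(profile, maxDepth = 200) {
        if (!is.numeric(maxDepth) || length(maxDepth) != 1L ||
            is.na(maxDepth) || maxDepth <= 0)
            stop("config error: 'maxDepth' must be a positive number")
        rec <- records(profile)
        snpProfile(lineId(profile), rec[rec$depth <= maxDepth, , drop = FALSE])
    })

#' Sequentially subtract sibling-line SNP profiles from a focal profile
#'
#' Removes from the focal profile every record whose key -- position, or
#' position plus alleles, per `matchMode` -- appears in any of the other
#' profiles, one profile at a time, recording the surviving count after each
#' subtraction.  SNPs shared between independently mutagenized lines cannot
#' be line-specific induced mutations; they are reference artifacts or
#' shared background, so presence in any sibling profile (regardless of that
#' profile's frequency or depth) removes the record.
#'
#' @param focal A [SnpProfile] (typically already frequency- and
#'   depth-filtered).
#' @param others Ordered list of [SnpProfile] from other lines; the focal
#'   line must not appear among them.
#' @param config A [FilterConfig] supplying `matchMode`.
#' @return A [CandidateReport] (candidates not yet annotated).
#' @examples
#' f <- snpProfile("a", data.frame(chrom = "chr1", pos = 1:3, ref = "G",
#'     alt = "A", alt_count = 99L, depth = 100L))
#' o <- snpProfile("b", data.frame(chrom = "chr1", pos = 2L, ref = "G",
#'     alt = "A", alt_count = 99L, depth = 100L))
#' stageCounts(subtractProfiles(f, list(o)))
#' @export
subtractProfiles <- function(focal, others, config = filterConfig()) {
    stopifnot(is(focal, "SnpProfile"))
    if (is(others, "SnpProfile")) others <- list(others)
    ids <- vapply(others, lineId, "")
    if (lineId(focal) %in% ids)
        stop("usage error: focal line '", lineId(focal),
             "' appears among the profiles to subtract")
    rec <- records(focal)
    stages <- data.frame(stage = "focal", count = nrow(rec),
                         stringsAsFactors = FALSE)
    for (other in others) {
        keys <- .recordKeys(rec, config@matchMode)
        otherKeys <- .recordKeys(records(other), config@matchMode)
        rec <- rec[!keys %in% otherKeys, , drop = FALSE]
        stages <- rbind(stages, data.frame(
            stage = paste0("minus_", lineId(other)), count = nrow(rec),
            stringsAsFactors = FALSE))
    }
    rownames(rec) <- NULL
    new("CandidateReport", focalLine = lineId(focal), stageCounts = stages,
        candidates = rec)
}

#' Run the full candidate-identification pipeline
#'
#' Applies, in order: the allele-frequency filter (retain frequency strictly
#' above `minFrequency`), the depth filter (discard depth strictly above
#' `maxDepth`), and the sequential subtraction of the other lines' profiles;
#' then, when a genome is supplied, annotates the survivors (coding effect,
#' replacement severity, repeat overlap) and ranks them by predicted
#' impact.  Every stage's surviving count is recorded in the report.
#'
#' @param focal A [SnpProfile], or the path of a VCF file to read.
#' @param others List of [SnpProfile] (or VCF paths) from sibling lines, in
#'   subtraction order.
#' @param genome Optional [GenomeModel] enabling annotation and ranking.
#' @param config A [FilterConfig].
#' @param scorer A [substitutionScorer()] for replacement-severity calls.
#' @return A [CandidateReport].
#' @export
runPipeline <- function(focal, others, genome = NULL,
                        config = filterConfig(),
                        scorer = substitutionScorer()) {
    validObject(config)
    if (is.character(focal)) focal <- readSnpVcf(focal)
    others <- lapply(others, function(o)
        if (is.character(o)) readSnpVcf(o) else o)

    raw <- nrow(records(focal))
    ff <- filterByFrequency(focal, config@minFrequency)
    fd <- filterByDepth(ff, config@maxDepth)
    rep0 <- subtractProfiles(fd, others, config)

    stages <- rbind(
        data.frame(stage = c("raw",
                             sprintf("frequency_gt_%g", config@minFrequency),
                             sprintf("depth_le_%g", config@maxDepth)),
                   count = c(raw, nrow(records(ff)), nrow(records(fd))),
                   stringsAsFactors = FALSE),
        stageCounts(rep0)[-1L, , drop = FALSE])
    rownames(stages) <- NULL

    cand <- candidates(rep0)
    if (!is.null(genome)) {
        cand <- annotateCandidates(cand, genome, scorer)
        cand <- rankCandidates(cand)
    }
    new("CandidateReport", focalLine = lineId(focal), stageCounts = stages,
        candidates = cand)
}
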