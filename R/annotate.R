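#' @importFrom Biostrings DNAString reverseComplement subseq matchPDict PDict
#'   vcountPDict GENETIC_CODE
NULL

.AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V")

#' Amino-acid substitution scorer
#'
#' A symmetric 20x20 amino-acid pair score table with a threshold below
#' which a replacement is called nonconservative.  The default table is
#' BLOSUM62 with threshold 0: replacements scoring negatively (e.g. M->K)
#' are "drastic", positively scoring ones (e.g. I->L) conservative.  This
#' operationalizes the by-eye severity judgement used when triaging
#' nonsynonymous candidates.
#'
#' @param matrix Symmetric numeric matrix covering the 20 standard amino
#'   acids (rows/columns named by one-letter code).
#' @param threshold Score strictly below which a pair is nonconservative.
#' @return A list with elements `matrix` and `threshold`.
#' @examples
#' sc <- substitutionScorer()
#' sc$matrix["M", "K"]
#' @export
substitutionScorer <- function(matrix = NULL, threshold = 0) {
    if (is.null(matrix)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        matrix <- e$BLOSUM62
    }
    if (!all(.AA_STANDARD %in% rownames(matrix)) ||
        !all(.AA_STANDARD %in% colnames(matrix)))
        stop("score table must cover all 20 standard amino acids")
    m <- matrix[.AA_STANDARD, .AA_STANDARD]
    if (!isSymmetric(unname(m)))
        stop("score table must be symmetric")
    list(matrix = m, threshold = threshold)
}

#' Classify an amino-acid replacement as conservative or not
#'
#' @param refAa,altAa One-letter codes of the reference and replacement
#'   residues.
#' @param scorer A [substitutionScorer()].
#' @return `"conservative"` or `"nonconservative"`.
#' @examples
#' classifyReplacement("M", "K")   # nonconservative (drastic)
#' classifyReplacement("I", "L")   # conservative
#' @export
classifyReplacement <- function(refAa, altAa, scorer = substitutionScorer()) {
    if (!refAa %in% .AA_STANDARD || !altAa %in% .AA_STANDARD)
        stop("input error: '", refAa, "'/'", altAa,
             "' is not a standard amino acid")
    if (scorer$matrix[refAa, altAa] < scorer$threshold)
        "nonconservative" else "conservative"
}

## CDS sequence of one gene in coding (5'->3') orientation, plus the map
## from genomic position to CDS coordinate
.cdsOf <- function(genome, gid) {
    g <- geneRanges(genome)
    g <- g[mcols(g)$gene_id == gid]
    g <- g[order(start(g))]
    chrom <- as.character(seqnames(g))[1]
    strand <- as.character(strand(g))[1]
    seqc <- chromSequences(genome)[[chrom]]
    pieces <- lapply(seq_along(g), function(i)
        as.character(subseq(seqc, start(g)[i], end(g)[i])))
    cds <- paste(pieces, collapse = "")
    genomicPos <- unlist(lapply(seq_along(g), function(i)
        seq(start(g)[i], end(g)[i])))
    if (strand == "-") {
        cds <- as.character(reverseComplement(DNAString(cds)))
        genomicPos <- rev(genomicPos)
    }
    list(cds = cds, genomicPos = genomicPos, strand = strand, chrom = chrom)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate the coding effect of a SNP
#'
#' Locates the position relative to the gene models: intergenic/intronic
#' SNPs are `noncoding`; for CDS positions the codon is reconstructed
#' respecting strand and exon order, translated with the standard genetic
#' code, and classified as `synonymous` or `nonsynonymous`.  Protein
#' coordinates are 1-based (codon 1 = start of the CDS).
#'
#' @param chrom,pos,ref,alt The SNP (1-based position; `ref` must match the
#'   reference base, checked).
#' @param genome A [GenomeModel].
#' @param genes CDS `GRanges`; defaults to `geneRanges(genome)`.
#' @return A list: `category` (`noncoding`/`synonymous`/`nonsynonymous`),
#'   `gene_id`, `ref_aa`, `codon_number`, `alt_aa`, `aa_change` (e.g.
#'   `"M371K"`, `NA` unless nonsynonymous), `in_repeat`.
#' @examples
#' g <- simulateGenome(simParams(genomeLength = 50000, seed = 1))
#' cds1 <- geneRanges(g)[1]
#' p <- GenomicRanges::start(cds1)
#' b <- as.character(Biostrings::subseq(chromSequences(g)[[1]], p, p))
#' annotateVariant("chr1", p, b, setdiff(c("A","C","G","T"), b)[1], g)$category
#' @export
annotateVariant <- function(chrom, pos, ref, alt, genome,
                            genes = geneRanges(genome)) {
    seqs <- chromSequences(genome)
    if (!chrom %in% names(seqs))
        stop("coordinate error: unknown chromosome '", chrom, "'")
    if (pos < 1 || pos > length(seqs[[chrom]]))
        stop("coordinate error: position ", pos, " outside ", chrom)
    refGenome <- as.character(subseq(seqs[[chrom]], pos, pos))
    if (refGenome != ref)
        stop("data-integrity error: ref allele '", ref, "' at ", chrom, ":",
             pos, " does not match reference base '", refGenome, "'")
    inRepeat <- length(GenomicRanges::findOverlaps(
        GRanges(chrom, IRanges(pos, pos)), repeatRanges(genome))) > 0

    hit <- GenomicRanges::findOverlaps(GRanges(chrom, IRanges(pos, pos)), genes)
    if (!length(hit))
        return(list(category = "noncoding", gene_id = NA_character_,
                    ref_aa = NA_character_, codon_number = NA_integer_,
                    alt_aa = NA_character_, aa_change = NA_character_,
                    in_repeat = inRepeat))

    gid <- mcols(genes)$gene_id[S4Vectors::subjectHits(hit)[1]]
    cdsInfo <- .cdsOf(genome, gid)
    cdsPos <- match(pos, cdsInfo$genomicPos)
    codonNumber <- (cdsPos - 1L) %/% 3L + 1L
    within <- (cdsPos - 1L) %% 3L + 1L
    codon <- substring(cdsInfo$cds, (codonNumber - 1L) * 3L + 1L,
                       codonNumber * 3L)
    altCoding <- if (cdsInfo$strand == "-") .COMPLEMENT[[alt]] else alt
    mutCodon <- codon
    substring(mutCodon, within, within) <- altCoding
    refAa <- GENETIC_CODE[[codon]]
    altAa <- GENETIC_CODE[[mutCodon]]
    if (refAa == altAa)
        return(list(category = "synonymous", gene_id = gid, ref_aa = refAa,
                    codon_number = codonNumber, alt_aa = altAa,
                    aa_change = NA_character_, in_repeat = inRepeat))
    list(category = "nonsynonymous", gene_id = gid, ref_aa = refAa,
         codon_number = codonNumber, alt_aa = altAa,
         aa_change = paste0(refAa, codonNumber, altAa), in_repeat = inRepeat)
}

#' Annotate every record of a candidate table
#'
#' @param rec `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genome A [GenomeModel].
#' @param scorer A [substitutionScorer()] used for the conservation call of
#'   nonsynonymous changes.
#' @return The table with columns `category`, `gene_id`, `aa_change`,
#'   `conservation` (`n/a` unless nonsynonymous) and `in_repeat` appended.
#' @export
annotateCandidates <- function(rec, genome, scorer = substitutionScorer()) {
    if (!nrow(rec)) {
        rec$category <- character(0); rec$gene_id <- character(0)
        rec$aa_change <- character(0); rec$conservation <- character(0)
        rec$in_repeat <- logical(0)
        return(rec)
    }
    eff <- lapply(seq_len(nrow(rec)), function(i)
        annotateVariant(rec$chrom[i], rec$pos[i], rec$ref[i], rec$alt[i],
                        genome))
    rec$category <- vapply(eff, `[[`, "", "category")
    rec$gene_id <- vapply(eff, `[[`, "", "gene_id")
    rec$aa_change <- vapply(eff, `[[`, "", "aa_change")
    ## gain or loss of a stop codon is drastic by definition; the scorer
    ## only judges residue-to-residue replacements
    rec$conservation <- vapply(eff, function(e) {
        if (e$category != "nonsynonymous") return("n/a")
        if (!all(c(e$ref_aa, e$alt_aa) %in% .AA_STANDARD))
            return("nonconservative")
        classifyReplacement(e$ref_aa, e$alt_aa, scorer)
    }, "")
    rec$in_repeat <- vapply(eff, `[[`, TRUE, "in_repeat")
    rec
}

#' Rank annotated candidates by predicted impact
#'
#' Severity order: nonsynonymous nonconservative, then nonsynonymous
#' conservative, then synonymous, then noncoding; ties broken by
#' (chromosome, position) for reproducibility.
#'
#' @param rec An annotated candidate table (see [annotateCandidates()]).
#' @return The table sorted by rank, with a `rank` column (1 = top).
#' @export
rankCandidates <- function(rec) {
    if (!nrow(rec)) { rec$rank <- integer(0); return(rec) }
    sev <- ifelse(rec$category == "nonsynonymous" &
                      rec$conservation == "nonconservative", 1L,
           ifelse(rec$category == "nonsynonymous", 2L,
           ifelse(rec$category == "synonymous", 3L, 4L)))
    o <- order(sev, rec$chrom, rec$pos)
    rec <- rec[o, , drop = FALSE]
    rec$rank <- seq_len(nrow(rec))
    rownames(rec) <- NULL
    rec
}

## does any length-L window of `frag` occur exactly in any of `subjects`?
.anyWindowMatch <- function(frag, subjects, L) {
    if (L < 1L) return(TRUE)
    if (L > nchar(frag)) return(FALSE)
    windows <- unique(substring(frag, seq_len(nchar(frag) - L + 1L),
                                seq_len(nchar(frag) - L + 1L) + L - 1L))
    pd <- PDict(DNAStringSet(windows))
    for (s in subjects)
        if (sum(Biostrings::countPDict(pd, s)) > 0) return(TRUE)
    FALSE
}

#' Scan a fragment for exact off-target matches in the genome
#'
#' Computes the longest exact contiguous match (either strand) between a
#' candidate RNAi fragment and the genome with the fragment's source locus
#' excluded, and compares it against a maximum tolerated block length.  The
#' selection rule for an RNAi trigger is that no other genomic region
#' perfectly matches the fragment for a contiguous block longer than the
#' threshold (default 16 bp, well below the ~21 nt small-RNA match needed
#' for silencing).
#'
#' @param fragment Character or `DNAString`; must occur at the source locus
#'   (forward or reverse strand), checked.
#' @param genome A [GenomeModel].
#' @param sourceChrom,sourceStart,sourceEnd The source locus (1-based,
#'   inclusive) excluded from the scan.
#' @param threshold Maximum tolerated off-target block length (default 16).
#' @return A list: `maxMatch` (bp; 0 when nothing outside the source locus
#'   matches at even 1 bp), `pass` (`maxMatch <= threshold`), `threshold`.
#' @export
offTargetScan <- function(fragment, genome, sourceChrom, sourceStart,
                          sourceEnd, threshold = 16) {
    frag <- toupper(as.character(fragment))
    if (nchar(frag) < 1L) stop("fragment must have length >= 1")
    seqs <- chromSequences(genome)
    if (!sourceChrom %in% names(seqs))
        stop("coordinate error: unknown chromosome '", sourceChrom, "'")
    locus <- as.character(subseq(seqs[[sourceChrom]], sourceStart, sourceEnd))
    fragRc <- as.character(reverseComplement(DNAString(frag)))
    if (locus != frag && locus != fragRc)
        stop("usage error: fragment does not match the genome at the ",
             "stated source locus")

    ## mask the source locus with N so exact matching cannot hit it
    masked <- as.character(seqs)
    substring(masked[sourceChrom], sourceStart, sourceEnd) <-
        paste(rep("N", sourceEnd - sourceStart + 1L), collapse = "")
    subjects <- lapply(masked, DNAString)
    subjects <- c(subjects, lapply(subjects, reverseComplement))

    ## binary search for the largest L with an exact window match
    lo <- 0L; hi <- nchar(frag)
    while (lo < hi) {
        mid <- as.integer((lo + hi + 1L) %/% 2L)
        if (.anyWindowMatch(frag, subjects, mid)) lo <- mid else hi <- mid - 1L
    }
    list(maxMatch = lo, pass = lo <= threshold, threshold = threshold)
}
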