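#' @importFrom VariantAnnotation readVcf writeVcf VCF VCFHeader info info<-
#'   meta meta<- ref alt
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList DataFrameList
#' @importFrom Biostrings readDNAStringSet writeXStringSet
NULL

#' Read a SNP profile from a VCF file
#'
#' Reads a VCF v4.2 site list with per-site depth (`DP`) and either an
#' alternate-observation count (`AO`) or an allele frequency (`AF`).
#' Frequencies are recomputed from `AO/DP` when both are present (`AF` is
#' used only as a fallback, with `alt_count` rounded from `AF*DP`).
#' Multi-allelic rows are split into biallelic records.  Records violating
#' the profile invariants (e.g. `AO > DP`) are rejected with a diagnostic
#' naming the offending record.
#'
#' @param path VCF file path.
#' @param lineId Line identifier; defaults to the file name without
#'   extension.
#' @return A [SnpProfile].
#' @export
readSnpVcf <- function(path, lineId = sub("\\.vcf(\\.gz)?$", "", basename(path))) {
    vcf <- VariantAnnotation::readVcf(path)
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    inf <- info(vcf)
    n <- length(rr)
    if (!n)
        return(snpProfile(lineId, data.frame(
            chrom = character(0), pos = integer(0), ref = character(0),
            alt = character(0), alt_count = integer(0), depth = integer(0),
            frequency = numeric(0))))
    if (!"DP" %in% colnames(inf))
        stop("format error: ", path, " lacks the required INFO field DP")
    hasAO <- "AO" %in% colnames(inf)
    hasAF <- "AF" %in% colnames(inf)
    if (!hasAO && !hasAF)
        stop("format error: ", path, " needs INFO field AO or AF")

    unl <- function(x) if (is(x, "List")) as.numeric(unlist(x)) else as.numeric(x)
    dp <- unl(inf$DP)
    rec <- data.frame(
        chrom = as.character(seqnames(rr)),
        pos = start(rr),
        ref = as.character(ref(vcf)),
        alt = as.character(alt(vcf)),
        depth = as.integer(dp),
        stringsAsFactors = FALSE)
    if (hasAO) {
        rec$alt_count <- as.integer(unl(inf$AO))
    } else {
        rec$alt_count <- as.integer(round(unl(inf$AF) * dp))
    }
    rec$frequency <- rec$alt_count / rec$depth

    bad <- which(is.na(rec$depth) | rec$depth <= 0 | is.na(rec$alt_count) |
                 rec$alt_count < 0 | rec$alt_count > rec$depth)
    if (length(bad))
        stop("format error in ", path, ": record ", bad[1], " (",
             rec$chrom[bad[1]], ":", rec$pos[bad[1]],
             ") violates 0 <= AO <= DP, DP > 0")
    rec <- rec[, c("chrom", "pos", "ref", "alt", "alt_count", "depth",
                   "frequency")]
    snpProfile(lineId, rec)
}

#' Write a SNP profile as VCF v4.2
#'
#' Emits one biallelic record per row with INFO fields `DP`, `AO`, `AF`.
#'
#' @param profile A [SnpProfile].
#' @param path Output path (plain text unless it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(profile, path) {
    rec <- records(profile)
    gr <- GRanges(rec$chrom, IRanges(rec$pos, width = 1L))
    names(gr) <- paste0(rec$chrom, "_", rec$pos, "_", rec$ref, "_", rec$alt)
    fixed <- DataFrame(
        REF = DNAStringSet(rec$ref),
        ALT = CharacterList(as.list(rec$alt)),
        QUAL = rep(NA_real_, nrow(rec)),
        FILTER = rep("PASS", nrow(rec)))
    inf <- DataFrame(DP = as.integer(rec$depth), AO = as.integer(rec$alt_count),
                     AF = rec$frequency)
    hdr <- VCFHeader(samples = character(0))
    meta(hdr) <- DataFrameList(fileformat = DataFrame(
        Value = "VCFv4.2", row.names = "fileformat"))
    info(hdr) <- DataFrame(
        Number = c("1", "1", "1"),
        Type = c("Integer", "Integer", "Float"),
        Description = c("Total read depth",
                        "Alternate allele observation count",
                        "Alternate allele frequency"),
        row.names = c("DP", "AO", "AF"))
    vcf <- VCF(rowRanges = gr, fixed = fixed, info = inf, collapsed = TRUE)
    metadata(vcf)$header <- hdr
    writeVcf(vcf, path)
    invisible(path)
}

#' Read chromosome sequences from FASTA
#'
#' Mixed-case input is normalized to upper case; names are truncated at the
#' first whitespace.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(path) {
    s <- readDNAStringSet(path)
    s <- DNAStringSet(toupper(as.character(s)))
    names(s) <- sub("\\s.*$", "", names(s))
    s
}

#' Write a genome model to FASTA and GFF3
#'
#' Chromosomes are written line-wrapped at 60 columns; gene CDS intervals as
#' GFF3 `CDS` features (1-based, inclusive) grouped by `ID`, repeat
#' intervals as `repeat_region` features.
#'
#' @param genome A [GenomeModel].
#' @param fastaPath,gffPath Output paths.
#' @return `invisible(NULL)`.
#' @export
writeGenomeModel <- function(genome, fastaPath, gffPath) {
    writeXStringSet(chromSequences(genome), fastaPath, width = 60L)
    g <- geneRanges(genome)
    feats <- GRanges()
    if (length(g)) {
        ## phase of each CDS segment: bases to skip to reach the next codon
        ## boundary, accumulated in coding (5'->3') order within each gene
        phase <- integer(length(g))
        for (gid in unique(mcols(g)$gene_id)) {
            i <- which(mcols(g)$gene_id == gid)
            ord <- if (as.character(strand(g))[i[1]] == "-")
                i[order(start(g)[i], decreasing = TRUE)]
            else i[order(start(g)[i])]
            prior <- c(0L, cumsum(width(g)[ord]))[seq_along(ord)]
            phase[ord] <- (3L - prior %% 3L) %% 3L
        }
        mcols(g) <- DataFrame(type = "CDS", ID = mcols(g)$gene_id,
                              phase = phase,
                              is_causal = tolower(as.character(mcols(g)$is_causal)))
        feats <- g
    }
    r <- repeatRanges(genome)
    if (length(r)) {
        mcols(r) <- DataFrame(type = "repeat_region",
                              ID = sprintf("repeat%03d", seq_along(r)),
                              phase = NA_integer_, is_causal = "false")
        feats <- c(feats, r)
    }
    mcols(feats)$source <- "bsaMap"
    rtracklayer::export(feats, gffPath, format = "gff3")
    invisible(NULL)
}

#' Read a genome model from FASTA and GFF3
#'
#' Inverse of [writeGenomeModel()].  CDS coordinates are checked against the
#' chromosome lengths.
#'
#' @param fastaPath,gffPath Input paths.
#' @return A [GenomeModel].
#' @export
readGenomeModel <- function(fastaPath, gffPath) {
    seqs <- readGenomeFasta(fastaPath)
    feats <- rtracklayer::import(gffPath, format = "gff3")
    bad <- !(as.character(seqnames(feats)) %in% names(seqs))
    if (any(bad))
        stop("consistency error: feature on unknown chromosome '",
             as.character(seqnames(feats))[which(bad)[1]], "'")
    lens <- width(seqs)[match(as.character(seqnames(feats)), names(seqs))]
    over <- end(feats) > lens | start(feats) < 1L
    if (any(over))
        stop("consistency error: feature ", which(over)[1],
             " exceeds chromosome bounds (", as.character(seqnames(feats))[which(over)[1]],
             ", 1..", lens[which(over)[1]], ")")
    isCds <- as.character(feats$type) == "CDS"
    genes <- feats[isCds]
    if (length(genes)) {
        gid <- as.character(mcols(genes)$ID)
        causal <- rep(FALSE, length(genes))
        if ("is_causal" %in% colnames(mcols(genes)))
            causal <- tolower(as.character(mcols(genes)$is_causal)) == "true"
        ord <- order(as.character(seqnames(genes)), start(genes))
        genes <- genes[ord]; gid <- gid[ord]; causal <- causal[ord]
        rank <- stats::ave(seq_along(gid), gid, FUN = seq_along)
        mcols(genes) <- DataFrame(gene_id = gid, exon_rank = as.integer(rank),
                                  is_causal = causal)
    } else genes <- GRanges()
    reps <- feats[as.character(feats$type) == "repeat_region"]
    mcols(reps) <- NULL
    genomeModel(seqs, genes, reps)
}

#' Write an F2 cohort as TSV
#'
#' One row per individual: causal dosage, phenotype, then one column of
#' marker dosage per marker.
#'
#' @param cohort An [F2Cohort].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeF2Cohort <- function(cohort, path) {
    df <- data.frame(causal_dosage = causalGenotypes(cohort),
                     phenotype = as.character(phenotypes(cohort)),
                     stringsAsFactors = FALSE)
    md <- markerDosage(cohort)
    if (ncol(md)) df <- cbind(df, as.data.frame(md, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a candidate report as TSV plus a JSON audit block
#'
#' The candidate table goes to `tsvPath` (one row per candidate, stable
#' column order); the per-stage survivor counts go to `jsonPath` as a JSON
#' object `{"focal_line": ..., "stages": [{"stage": ..., "count": ...}]}`.
#'
#' @param report A [CandidateReport].
#' @param tsvPath,jsonPath Output paths (either may be `NULL` to skip).
#' @return `invisible(NULL)`.
#' @export
writeCandidateReport <- function(report, tsvPath = NULL, jsonPath = NULL) {
    if (!is.null(tsvPath))
        utils::write.table(candidates(report), tsvPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    if (!is.null(jsonPath))
        jsonlite::write_json(
            list(focal_line = lineId(report), stages = stageCounts(report)),
            jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}
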