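test_that("intergenic SNPs are noncoding and repeat overlap is flagged", {
    g <- tinyGenome()
    base <- function(pos) as.character(Biostrings::subseq(
        chromSequences(g)[["chrA"]], pos, pos))
    eff <- annotateVariant("chrA", 100, base(100),
                           setdiff(c("A", "C", "G", "T"), base(100))[1], g)
    expect_equal(eff$category, "noncoding")
    expect_false(eff$in_repeat)
    effRep <- annotateVariant("chrA", 3100, base(3100),
                              setdiff(c("A", "C", "G", "T"), base(3100))[1], g)
    expect_equal(effRep$category, "noncoding")
    expect_true(effRep$in_repeat)
})

test_that("annotation errors on ref mismatch and out-of-range coordinates", {
    g <- tinyGenome()
    base <- as.character(Biostrings::subseq(chromSequences(g)[["chrA"]], 10, 10))
    wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
    expect_error(annotateVariant("chrA", 10, wrong, base, g), "data-integrity")
    expect_error(annotateVariant("chrA", 99999, "A", "C", g), "coordinate")
    expect_error(annotateVariant("chrZ", 10, "A", "C", g), "coordinate")
})

test_that("a T>A at the second base of codon 371 (ATG) is called M371K", {
    g <- tinyGenome()
    pos <- 501L + (371L - 1L) * 3L + 1L   # second base of codon 371
    eff <- annotateVariant("chrA", pos, "T", "A", g)
    expect_equal(eff$category, "nonsynonymous")
    expect_equal(eff$aa_change, "M371K")
    expect_equal(eff$codon_number, 371L)
})

test_that("third-position degeneracy yields synonymous calls", {
    # build a chromosome whose first codon is GGA; G at position 3 -> GGG
    seqs <- Biostrings::DNAStringSet(paste0(
        "GGA", strrep("ACT", 3), "TAAACGTACGT"))
    names(seqs) <- "c"
    genes <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 15), strand = "+")
    S4Vectors::mcols(genes)$gene_id <- "g1"
    S4Vectors::mcols(genes)$exon_rank <- 1L
    S4Vectors::mcols(genes)$is_causal <- TRUE
    g <- genomeModel(seqs, genes)
    eff <- annotateVariant("c", 3, "A", "G", g)
    expect_equal(eff$category, "synonymous")
    expect_equal(eff$ref_aa, "G")
})

test_that("annotation is invariant under reverse-complementing the fixture", {
    g <- tinyGenome()
    chrLen <- length(chromSequences(g)[["chrA"]])
    # mirror genome: reverse-complemented chromosome, gene on minus strand
    rcSeq <- Biostrings::reverseComplement(chromSequences(g)[["chrA"]])
    seqs2 <- Biostrings::DNAStringSet(list(chrA = rcSeq))
    gr <- geneRanges(g)
    genes2 <- GenomicRanges::GRanges("chrA",
        IRanges::IRanges(chrLen - GenomicRanges::end(gr) + 1L,
                         chrLen - GenomicRanges::start(gr) + 1L),
        strand = "-")
    S4Vectors::mcols(genes2) <- S4Vectors::mcols(gr)
    g2 <- genomeModel(seqs2, genes2)
    pos <- 501L + (371L - 1L) * 3L + 1L
    eff1 <- annotateVariant("chrA", pos, "T", "A", g)
    eff2 <- annotateVariant("chrA", chrLen - pos + 1L, "A", "T", g2)
    expect_equal(eff2$aa_change, eff1$aa_change)
    expect_equal(eff2$category, eff1$category)
})

test_that("per-codon annotation agrees with full-CDS translation for every CDS position and alt base", {
    # two-exon gene on the minus strand exercises interval order and strand
    set.seed(55)
    chrLen <- 600L
    seqc <- paste(sample(c("A", "C", "G", "T"), chrLen, replace = TRUE),
                  collapse = "")
    seqs <- Biostrings::DNAStringSet(seqc); names(seqs) <- "c"
    genes <- GenomicRanges::GRanges("c",
        IRanges::IRanges(c(101L, 221L), c(160L, 280L)), strand = "-")
    S4Vectors::mcols(genes)$gene_id <- "g1"
    S4Vectors::mcols(genes)$exon_rank <- 1:2
    S4Vectors::mcols(genes)$is_causal <- TRUE
    g <- genomeModel(seqs, genes)

    oracleProtein <- function(sequence) {
        ex1 <- substring(sequence, 101, 160)
        ex2 <- substring(sequence, 221, 280)
        cds <- Biostrings::reverseComplement(
            Biostrings::DNAString(paste0(ex1, ex2)))
        as.character(Biostrings::translate(cds, no.init.codon = TRUE))
    }
    refProt <- oracleProtein(seqc)
    cdsPositions <- c(101:160, 221:280)
    for (pos in cdsPositions) {
        refb <- substring(seqc, pos, pos)
        for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
            eff <- annotateVariant("c", pos, refb, altb, g)
            mutSeq <- seqc
            substring(mutSeq, pos, pos) <- altb
            mutProt <- oracleProtein(mutSeq)
            diffAt <- which(strsplit(refProt, "")[[1]] !=
                            strsplit(mutProt, "")[[1]])
            if (length(diffAt) == 0L) {
                expect_equal(eff$category, "synonymous")
            } else {
                expect_equal(eff$category, "nonsynonymous")
                expect_equal(eff$codon_number, diffAt)
                expect_equal(eff$aa_change, paste0(
                    substring(refProt, diffAt, diffAt), diffAt,
                    substring(mutProt, diffAt, diffAt)))
            }
        }
    }
})

test_that("replacement severity follows the substitution score sign", {
    expect_equal(classifyReplacement("M", "M"), "conservative")
    expect_equal(classifyReplacement("M", "K"), "nonconservative")
    expect_equal(classifyReplacement("I", "L"), "conservative")
    expect_error(classifyReplacement("M", "*"), "input error")
    sc <- substitutionScorer()
    expect_true(isSymmetric(unname(sc$matrix)))
    expect_equal(dim(sc$matrix), c(20L, 20L))
})

test_that("candidates rank by severity with coordinate tie-breaks", {
    rec <- data.frame(
        chrom = c("chr1", "chr1", "chr1", "chr1", "chr1"),
        pos = c(500L, 100L, 50L, 300L, 200L),
        ref = "G", alt = "A",
        category = c("noncoding", "synonymous", "nonsynonymous",
                     "nonsynonymous", "nonsynonymous"),
        conservation = c("n/a", "n/a", "nonconservative", "conservative",
                         "nonconservative"),
        stringsAsFactors = FALSE)
    ranked <- rankCandidates(rec)
    expect_equal(ranked$pos, c(50L, 200L, 300L, 100L, 500L))
    expect_equal(ranked$rank, 1:5)
})

test_that("the planted causal SNP is the top-ranked candidate end to end", {
    sc <- defaultScenario()
    rep <- runPipeline(sc$profiles[[1]], sc$profiles[-1], genome = sc$genome)
    cs <- causalSnp(sc$lines[[1]])
    top <- candidates(rep)[1, ]
    expect_equal(top$rank, 1L)
    expect_equal(c(top$chrom, top$pos, top$ref, top$alt),
                 c(cs$chrom, cs$pos, cs$ref, cs$alt))
})

test_that("off-target scan matches the quadratic all-substring oracle", {
    p <- simParams(genomeLength = 12000, nChromosomes = 1, nGenes = 1,
                   cdsLength = 300, seed = 9)
    g <- simulateGenome(p)
    frag <- as.character(Biostrings::subseq(chromSequences(g)[[1]],
                                            2001, 2100))
    got <- offTargetScan(frag, g, "chr1", 2001, 2100)
    expect_equal(got$maxMatch,
                 bruteLongestMatch(frag, g, "chr1", 2001, 2100))
    # random 12 kb genome: chance matches stay short
    expect_lt(got$maxMatch, 30)
})

test_that("a planted 25 bp copy elsewhere fails the off-target criterion", {
    p <- simParams(genomeLength = 12000, nChromosomes = 1, nGenes = 1,
                   cdsLength = 300, seed = 10)
    g <- simulateGenome(p)
    seqc <- as.character(chromSequences(g)[[1]])
    frag <- substring(seqc, 3001, 3100)
    substring(seqc, 8001, 8025) <- substring(frag, 40, 64)   # plant a copy
    seqs <- Biostrings::DNAStringSet(seqc); names(seqs) <- "chr1"
    g2 <- genomeModel(seqs, geneRanges(g), repeatRanges(g))
    got <- offTargetScan(frag, g2, "chr1", 3001, 3100)
    expect_gte(got$maxMatch, 25)
    expect_false(got$pass)
    # reverse-complement hits count too
    seqc2 <- as.character(chromSequences(g)[[1]])
    rcpart <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substring(frag, 40, 64))))
    substring(seqc2, 8001, 8025) <- rcpart
    seqs2 <- Biostrings::DNAStringSet(seqc2); names(seqs2) <- "chr1"
    g3 <- genomeModel(seqs2, geneRanges(g), repeatRanges(g))
    expect_gte(offTargetScan(frag, g3, "chr1", 3001, 3100)$maxMatch, 25)
})

test_that("off-target scan rejects a fragment absent from the source locus", {
    g <- tinyGenome()
    expect_error(offTargetScan("ACGTACGTACGT", g, "chrA", 1, 12),
                 "usage error")
    # degenerate: fragment is the whole chromosome; nothing remains outside
    whole <- as.character(chromSequences(g)[["chrA"]])
    got <- offTargetScan(whole, g, "chrA", 1, nchar(whole))
    expect_equal(got$maxMatch, 0L)
    expect_true(got$pass)
})
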