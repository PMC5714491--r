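#' Default simulation parameters
#'
#' Returns a validated [SimParams] object.  Defaults encode the mapping
#' design the pipeline targets: an F2 population of 455 individuals
#' segregating 1:2:1 at one causal locus, a pool of 96 phenotype-selected
#' homozygous mutants sequenced to ~100x, mutagenized lines carrying ~50
#' induced point mutations dominated (99 percent) by the G:C->A:T
#' transitions characteristic of EMS, and a background of artifactual
#' high-frequency SNPs shared across lines, a fraction of them at the
#' excessive depths typical of collapsed repeats.
#'
#' @param genomeLength Total genome size in bp (default 200000).
#' @param nChromosomes Number of equally sized chromosomes (default 2).
#' @param nGenes Number of simulated genes (default 4).
#' @param cdsLength CDS length per gene, bp, divisible by 3 (default 900).
#' @param nRepeats,repeatLength Repeat-flagged intervals (default 12 x 500 bp).
#' @param nInducedSnps Induced SNPs per line (default 50).
#' @param emsTransitionFraction Fraction of induced SNPs that are G->A or
#'   C->T (default 0.99).
#' @param nF2 F2 cohort size (default 455).
#' @param cmPerMb Map density for same-chromosome recombination fractions
#'   (default 5 cM/Mb, Haldane, no interference).
#' @param poolSize Individuals pooled for sequencing (default 96).
#' @param meanDepth,depthDispersion Negative-binomial depth model
#'   (default mean 100, size 5).
#' @param baseErrorRate Per-read symmetric allele flip (default 0.001).
#' @param nArtifactSnps Shared artifact SNPs (default 100).
#' @param artifactFrequencyRange Artifact frequency interval
#'   (default `c(0.9, 1)`).
#' @param artifactHighdepthFraction Fraction of artifacts given depth above
#'   the default 200x cutoff (default 0.3).
#' @param seed Integer RNG seed (default 1).
#' @return A [SimParams].
#' @examples
#' simParams(nF2 = 100, seed = 7)
#' @export
simParams <- function(genomeLength = 200000, nChromosomes = 2, nGenes = 4,
                      cdsLength = 900, nRepeats = 12, repeatLength = 500,
                      nInducedSnps = 50, emsTransitionFraction = 0.99,
                      nF2 = 455, cmPerMb = 5, poolSize = 96,
                      meanDepth = 100, depthDispersion = 5,
                      baseErrorRate = 0.001, nArtifactSnps = 100,
                      artifactFrequencyRange = c(0.9, 1),
                      artifactHighdepthFraction = 0.3, seed = 1) {
    new("SimParams", genomeLength = genomeLength, nChromosomes = nChromosomes,
        nGenes = nGenes, cdsLength = cdsLength, nRepeats = nRepeats,
        repeatLength = repeatLength, nInducedSnps = nInducedSnps,
        emsTransitionFraction = emsTransitionFraction, nF2 = nF2,
        cmPerMb = cmPerMb, poolSize = poolSize, meanDepth = meanDepth,
        depthDispersion = depthDispersion, baseErrorRate = baseErrorRate,
        nArtifactSnps = nArtifactSnps,
        artifactFrequencyRange = artifactFrequencyRange,
        artifactHighdepthFraction = artifactHighdepthFraction, seed = seed)
}

.BASES <- c("A", "C", "G", "T")

#' Simulate a reference genome with gene models and repeats
#'
#' Draws uniform-random chromosome sequences, places non-overlapping
#' two-exon genes (the first flagged as the causal gene), and flags repeat
#' intervals in the intergenic space.  Deterministic under a fixed seed.
#'
#' @param params A [SimParams]; `params@seed` seeds the RNG unless `seed`
#'   is given.
#' @param seed Optional integer overriding `params@seed`.
#' @return A [GenomeModel] with at least one causal gene.
#' @examples
#' g <- simulateGenome(simParams(genomeLength = 50000, seed = 1))
#' g
#' @export
simulateGenome <- function(params = simParams(), seed = params@seed) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    totalCds <- params@nGenes * params@cdsLength
    if (params@genomeLength < 3 * totalCds)
        stop("invalid 'genomeLength': must be at least 3x the total ",
             "requested CDS length (", 3 * totalCds, " bp)")
    if (params@nGenes < 1)
        stop("invalid 'nGenes': at least one (causal) gene is required")
    set.seed(seed)

    chrLen <- floor(params@genomeLength / params@nChromosomes)
    chrNames <- sprintf("chr%d", seq_len(params@nChromosomes))
    seqs <- DNAStringSet(vapply(chrNames, function(nm)
        paste(sample(.BASES, chrLen, replace = TRUE), collapse = ""),
        character(1)))
    names(seqs) <- chrNames

    # two exons per gene, intron fixed at 150 bp; genes tiled left to right
    # with random gaps so they never overlap
    exon1 <- ceiling(params@cdsLength / 2)
    exon1 <- exon1 + (3 - (exon1 %% 3)) %% 3      # keep exon1 in frame
    exon2 <- params@cdsLength - exon1
    intron <- 150L
    geneSpan <- params@cdsLength + intron
    perChr <- ceiling(params@nGenes / params@nChromosomes)

    gChrom <- gStart <- gWidth <- gStrand <- gId <- gRank <- gCausal <- list()
    gid <- 0L
    for (ci in seq_len(params@nChromosomes)) {
        nHere <- min(perChr, params@nGenes - gid)
        if (nHere <= 0) break
        slack <- chrLen - nHere * geneSpan
        gaps <- floor(slack * diff(c(0, sort(stats::runif(nHere)))))
        cursor <- 0L
        for (k in seq_len(nHere)) {
            gid <- gid + 1L
            cursor <- cursor + gaps[k]
            startPos <- cursor + 1L
            i <- length(gChrom) + 1L
            gChrom[[i]] <- rep(chrNames[ci], 2L)
            gStart[[i]] <- c(startPos, startPos + exon1 + intron)
            gWidth[[i]] <- c(exon1, exon2)
            gStrand[[i]] <- rep(sample(c("+", "-"), 1L), 2L)
            gId[[i]] <- rep(sprintf("gene%02d", gid), 2L)
            gRank[[i]] <- 1:2
            gCausal[[i]] <- rep(gid == 1L, 2L)
            cursor <- cursor + geneSpan
        }
    }
    genes <- GRanges(unlist(gChrom),
                     IRanges(unlist(gStart), width = unlist(gWidth)),
                     strand = unlist(gStrand),
                     seqlengths = stats::setNames(rep(chrLen, length(chrNames)),
                                                  chrNames))
    mcols(genes)$gene_id <- unlist(gId)
    mcols(genes)$exon_rank <- unlist(gRank)
    mcols(genes)$is_causal <- unlist(gCausal)

    # repeats drawn from intergenic space
    rChrom <- character(0); rStart <- integer(0)
    tries <- 0L
    while (length(rChrom) < params@nRepeats && tries < 500L) {
        tries <- tries + 1L
        ci <- sample(params@nChromosomes, 1L)
        st <- sample(chrLen - params@repeatLength, 1L)
        cand <- GRanges(chrNames[ci], IRanges(st, width = params@repeatLength))
        hitsGene <- length(GenomicRanges::findOverlaps(cand, genes)) > 0
        hitsRep <- length(rChrom) &&
            any(rChrom == chrNames[ci] &
                abs(rStart - st) < params@repeatLength)
        if (!hitsGene && !hitsRep) {
            rChrom <- c(rChrom, chrNames[ci])
            rStart <- c(rStart, st)
        }
    }
    reps <- GRanges(rChrom, IRanges(rStart, width = params@repeatLength),
                    seqlengths = stats::setNames(rep(chrLen, length(chrNames)),
                                                 chrNames))
    genomeModel(seqs, genes, reps)
}

## substitution respecting the EMS spectrum: G->A / C->T transitions with
## probability emsTransitionFraction, otherwise any other change
.drawSnp <- function(seqChar, nmChar, offsets, isTransition) {
    refs <- substring(seqChar[nmChar], offsets, offsets)
    alt <- character(length(refs))
    alt[isTransition] <- ifelse(refs[isTransition] == "G", "A", "T")
    for (i in which(!isTransition)) {
        choices <- setdiff(.BASES, refs[i])
        if (refs[i] == "G") choices <- setdiff(choices, "A")
        if (refs[i] == "C") choices <- setdiff(choices, "T")
        alt[i] <- sample(choices, 1L)
    }
    data.frame(ref = refs, alt = alt, stringsAsFactors = FALSE)
}

#' Simulate an EMS-mutagenized line
#'
#' Plants exactly one causal SNP -- a nonsynonymous, nonconservative
#' (drastic) amino-acid replacement in the causal gene, emulating a
#' loss-of-function lesion -- plus `nInducedSnps - 1` background SNPs at
#' positions drawn uniformly over the genome.  Substitution types follow the
#' EMS spectrum: a fraction `emsTransitionFraction` are G->A or C->T (drawn
#' at G/C sites); the remainder are arbitrary other changes.
#'
#' @param genome A [GenomeModel] containing a causal gene.
#' @param params A [SimParams].
#' @param lineId Identifier for the line.
#' @param seed Integer seed (default `params@seed`); vary it to obtain
#'   independent sibling lines from the same genome.
#' @return A [MutantLine].
#' @examples
#' g <- simulateGenome(simParams(genomeLength = 50000, seed = 1))
#' simulateMutantLine(g, simParams(nInducedSnps = 10), lineId = "m1", seed = 2)
#' @export
simulateMutantLine <- function(genome, params = simParams(), lineId = "mut1",
                               seed = params@seed) {
    stopifnot(is(genome, "GenomeModel"))
    validObject(params)
    genes <- geneRanges(genome)
    causal <- genes[mcols(genes)$is_causal]
    if (!length(causal))
        stop("genome has no causal gene")
    set.seed(seed)

    seqChar <- as.character(chromSequences(genome))
    chrLen <- nchar(seqChar)

    ## causal SNP: scan shuffled CDS positions for a drastic
    ## (negative-score) amino-acid replacement, preferring the EMS spectrum
    gid <- mcols(causal)$gene_id[1]
    cdsPos <- unlist(lapply(seq_along(causal), function(i)
        seq(start(causal)[i], end(causal)[i])))
    chrom <- as.character(seqnames(causal))[1]
    found <- NULL
    scorer <- substitutionScorer()
    for (pos in sample(cdsPos)) {
        refb <- substring(seqChar[chrom], pos, pos)
        altOrder <- if (refb %in% c("G", "C"))
            c(ifelse(refb == "G", "A", "T"),
              sample(setdiff(.BASES, c(refb, ifelse(refb == "G", "A", "T")))))
        else sample(setdiff(.BASES, refb))
        for (altb in altOrder) {
            eff <- annotateVariant(chrom, pos, refb, altb, genome)
            if (eff$category == "nonsynonymous" &&
                eff$ref_aa %in% .AA_STANDARD && eff$alt_aa %in% .AA_STANDARD &&
                classifyReplacement(eff$ref_aa, eff$alt_aa, scorer) ==
                    "nonconservative") {
                found <- data.frame(chrom = chrom, pos = pos, ref = refb,
                                    alt = altb, causal = TRUE,
                                    stringsAsFactors = FALSE)
                break
            }
        }
        if (!is.null(found)) break
    }
    if (is.null(found))
        stop("simulation error: no nonsynonymous site available in the ",
             "causal gene '", gid, "'")

    nOther <- params@nInducedSnps - 1L
    snps <- found
    if (nOther > 0) {
        chromV <- posV <- character(0)
        takenKey <- paste(found$chrom, found$pos)
        isTrans <- stats::runif(nOther) < params@emsTransitionFraction
        rows <- vector("list", nOther)
        for (i in seq_len(nOther)) {
            repeat {
                ci <- sample(names(seqChar), 1L)
                p <- sample(chrLen[[ci]], 1L)
                refb <- substring(seqChar[ci], p, p)
                if (isTrans[i] && !(refb %in% c("G", "C"))) next
                key <- paste(ci, p)
                if (key %in% takenKey) next
                takenKey <- c(takenKey, key)
                sub <- .drawSnp(seqChar, ci, p, isTrans[i])
                rows[[i]] <- data.frame(chrom = ci, pos = p, ref = sub$ref,
                                        alt = sub$alt, causal = FALSE,
                                        stringsAsFactors = FALSE)
                break
            }
        }
        snps <- rbind(snps, do.call(rbind, rows))
    }
    snps <- snps[order(snps$chrom, snps$pos), ]
    rownames(snps) <- NULL
    new("MutantLine", lineId = lineId, snps = snps)
}

## recombination fraction of each marker with the causal locus:
## same chromosome -> Haldane map from physical distance; otherwise 0.5
.markerRecFractions <- function(line, params) {
    cs <- causalSnp(line)
    mk <- inducedSnps(line)
    mk <- mk[!mk$causal, , drop = FALSE]
    r <- rep(0.5, nrow(mk))
    same <- mk$chrom == cs$chrom
    if (any(same)) {
        dMorgan <- abs(mk$pos[same] - cs$pos) / 1e6 * params@cmPerMb / 100
        r[same] <- 0.5 * (1 - exp(-2 * dMorgan))
    }
    data.frame(chrom = mk$chrom, pos = mk$pos, ref = mk$ref, alt = mk$alt,
               r = r, stringsAsFactors = FALSE)
}

#' Simulate an F2 cohort segregating at the causal locus
#'
#' Each individual receives two independent gametes; each gamete carries the
#' mutant causal allele with probability 1/2, and co-transmits each marker's
#' mutant allele with probability `1 - r` (an independent recombination
#' event per marker, no interference).  Phenotype is the deterministic map
#' of causal dosage: 0 -> `light`, 1 -> `dark`, 2 -> `very_pale`.
#'
#' @param genome A [GenomeModel] (used only for marker bookkeeping).
#' @param line A [MutantLine] whose non-causal SNPs become the markers.
#' @param params A [SimParams]; `nF2` individuals are drawn.
#' @param markerR Optional numeric vector overriding the per-marker
#'   recombination fractions derived from the genetic map (recycled).
#' @param seed Integer seed (default `params@seed`).
#' @return An [F2Cohort].
#' @export
simulateF2 <- function(genome, line, params = simParams(), markerR = NULL,
                       seed = params@seed) {
    stopifnot(is(line, "MutantLine"))
    validObject(params)
    set.seed(seed)
    n <- as.integer(params@nF2)
    info <- .markerRecFractions(line, params)
    if (!is.null(markerR)) {
        if (any(markerR < 0 | markerR > 0.5))
            stop("invalid 'markerR': recombination fractions must lie in [0, 0.5]")
        info$r <- rep_len(markerR, nrow(info))
    }
    m <- nrow(info)

    g1 <- stats::rbinom(n, 1L, 0.5)   # maternal gamete causal allele
    g2 <- stats::rbinom(n, 1L, 0.5)   # paternal gamete causal allele
    geno <- as.integer(g1 + g2)

    dos <- matrix(0L, nrow = n, ncol = m)
    if (m > 0) {
        for (j in seq_len(m)) {
            rec1 <- stats::rbinom(n, 1L, info$r[j])
            rec2 <- stats::rbinom(n, 1L, info$r[j])
            dos[, j] <- as.integer(xor(g1, rec1)) + as.integer(xor(g2, rec2))
        }
        colnames(dos) <- paste0(info$chrom, ":", info$pos)
    }
    phen <- factor(.PHENOTYPE_LEVELS[geno + 1L], levels = .PHENOTYPE_LEVELS)
    new("F2Cohort", genotypes = geno, phenotypes = phen,
        markerDosage = dos, markerInfo = info)
}

#' Pool phenotype-selected individuals and simulate pooled sequencing
#'
#' Selects `poolSize` individuals of the requested phenotype class (pooled
#' with equal representation), computes the pool allele frequency at the
#' causal SNP and every marker, and draws per-site read counts: depth from a
#' negative binomial with mean `meanDepth` and size `depthDispersion`, and
#' the alternate-read count from a binomial whose success probability is the
#' pool frequency perturbed by a symmetric per-read error
#' (`p(1-e) + (1-p)e`).  Sites drawn at zero depth are omitted.
#'
#' @param cohort An [F2Cohort].
#' @param line The [MutantLine] the cohort derives from.
#' @param params A [SimParams].
#' @param selectPhenotype Phenotype class to pool; default `"very_pale"`
#'   (causal-locus homozygous mutants).
#' @param seed Integer seed (default `params@seed`).
#' @return A [SnpProfile] for `lineId(line)`.
#' @export
poolAndSequence <- function(cohort, line, params = simParams(),
                            selectPhenotype = "very_pale",
                            seed = params@seed) {
    stopifnot(is(cohort, "F2Cohort"), is(line, "MutantLine"))
    validObject(params)
    selectPhenotype <- match.arg(selectPhenotype, .PHENOTYPE_LEVELS)
    set.seed(seed)
    idx <- which(as.character(phenotypes(cohort)) == selectPhenotype)
    k <- as.integer(params@poolSize)
    if (length(idx) < k)
        stop("sampling error: only ", length(idx), " individuals of class '",
             selectPhenotype, "' available, ", k, " requested (shortfall ",
             k - length(idx), ")")
    pool <- sample(idx, k)

    cs <- causalSnp(line)
    info <- markerInfo(cohort)
    sites <- rbind(
        data.frame(chrom = cs$chrom, pos = cs$pos, ref = cs$ref,
                   alt = cs$alt, stringsAsFactors = FALSE),
        info[, c("chrom", "pos", "ref", "alt")])
    p <- c(mean(causalGenotypes(cohort)[pool]) / 2,
           if (nrow(info)) colMeans(markerDosage(cohort)[pool, , drop = FALSE]) / 2
           else numeric(0))

    depth <- as.integer(stats::rnbinom(nrow(sites), mu = params@meanDepth,
                                       size = params@depthDispersion))
    e <- params@baseErrorRate
    pObs <- p * (1 - e) + (1 - p) * e
    alt <- stats::rbinom(nrow(sites), depth, pObs)

    keep <- depth > 0L
    rec <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                      ref = sites$ref[keep], alt = sites$alt[keep],
                      alt_count = alt[keep], depth = depth[keep],
                      frequency = alt[keep] / depth[keep],
                      stringsAsFactors = FALSE)
    rec <- rec[order(rec$chrom, rec$pos), ]
    rownames(rec) <- NULL
    snpProfile(lineId(line), rec)
}

#' Inject shared artifactual SNPs into a set of profiles
#'
#' Adds `nArtifactSnps` artifact records at identical positions and alleles
#' to every profile, emulating the high-frequency calls that arise from
#' reference assembly errors and nonspecific mapping of repeats and that are
#' therefore shared between the SNP profiles of independent lines.
#' Positions are drawn preferentially (80 percent when repeat intervals
#' exist) from repeat-flagged intervals; per profile, each artifact gets a
#' frequency uniform in `artifactFrequencyRange`; a fraction
#' `artifactHighdepthFraction` of artifacts (the same ones in every profile)
#' receive excessive depth, uniform in (200, 1000], the rest
#' negative-binomial depth as for real sites.
#'
#' @param profiles List of at least two [SnpProfile] objects.
#' @param genome The [GenomeModel] the profiles refer to.
#' @param params A [SimParams].
#' @param seed Integer seed (default `params@seed`).
#' @return List of [SnpProfile] with artifacts appended; the artifact table
#'   is attached as `attr(, "artifacts")`.
#' @export
injectArtifacts <- function(profiles, genome, params = simParams(),
                            seed = params@seed) {
    if (!is.list(profiles) || length(profiles) < 2L)
        stop("at least two profiles are required (artifacts are defined by ",
             "being shared)")
    validObject(params)
    nA <- as.integer(params@nArtifactSnps)
    if (nA == 0L) {
        attr(profiles, "artifacts") <- data.frame()
        return(profiles)
    }
    set.seed(seed)
    seqChar <- as.character(chromSequences(genome))
    reps <- repeatRanges(genome)

    usedKeys <- unique(unlist(lapply(profiles, function(p)
        paste(records(p)$chrom, records(p)$pos))))
    arts <- vector("list", nA)
    i <- 0L
    while (i < nA) {
        inRepeat <- length(reps) > 0 && stats::runif(1) < 0.8
        if (inRepeat) {
            ri <- sample(length(reps), 1L)
            ci <- as.character(seqnames(reps))[ri]
            p <- sample(seq(start(reps)[ri], end(reps)[ri]), 1L)
        } else {
            ci <- sample(names(seqChar), 1L)
            p <- sample(nchar(seqChar[[ci]]), 1L)
        }
        key <- paste(ci, p)
        if (key %in% usedKeys) next
        usedKeys <- c(usedKeys, key)
        i <- i + 1L
        refb <- substring(seqChar[ci], p, p)
        arts[[i]] <- data.frame(chrom = ci, pos = p, ref = refb,
                                alt = sample(setdiff(.BASES, refb), 1L),
                                in_repeat = inRepeat, stringsAsFactors = FALSE)
    }
    arts <- do.call(rbind, arts)
    arts$highdepth <- stats::runif(nA) < params@artifactHighdepthFraction

    fr <- params@artifactFrequencyRange
    out <- lapply(profiles, function(prof) {
        depth <- as.integer(ifelse(arts$highdepth,
                        sample(201:1000, nA, replace = TRUE),
                        pmax(1, stats::rnbinom(nA, mu = params@meanDepth,
                                               size = params@depthDispersion))))
        altc <- as.integer(pmin(depth, round(stats::runif(nA, fr[1], fr[2]) *
                                             depth)))
        rec <- rbind(records(prof),
                     data.frame(chrom = arts$chrom, pos = arts$pos,
                                ref = arts$ref, alt = arts$alt,
                                alt_count = altc, depth = depth,
                                frequency = altc / depth,
                                stringsAsFactors = FALSE))
        rec <- rec[order(rec$chrom, rec$pos), ]
        rownames(rec) <- NULL
        snpProfile(lineId(prof), rec)
    })
    attr(out, "artifacts") <- arts
    out
}

#' Toy dose-response for flower color intensity
#'
#' An explicitly invented illustration (no kinetic model is claimed by the
#' mapping design) of how intermediate functional dosage of a
#' substrate-competing enzyme can maximize pigment intensity: pigment
#' production falls with dosage `d` as `1/(1 + kappa * d)` (substrate
#' competition) while pigment retention rises as
#' `(epsilon + d)/(epsilon + d + K)` (copigment stabilization).  With the
#' default constants intensity(0.5) > intensity(1) > intensity(0), the
#' heterozygote-darkest (overdominant) pattern.
#'
#' @param dosage Functional enzyme dosage in `[0, 1]` (0 = homozygous
#'   mutant, 0.5 = heterozygote, 1 = wild type).
#' @param kappa Competition strength (default 2).
#' @param epsilon Baseline copigment level (default 0.02).
#' @param K Half-saturation of the retention term (default 0.15).
#' @return Numeric intensity, arbitrary units.
#' @examples
#' colorIntensity(c(0, 0.5, 1))
#' @export
colorIntensity <- function(dosage, kappa = 2, epsilon = 0.02, K = 0.15) {
    stopifnot(all(dosage >= 0))
    production <- 1 / (1 + kappa * dosage)
    retention <- (epsilon + dosage) / (epsilon + dosage + K)
    production * retention
}
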