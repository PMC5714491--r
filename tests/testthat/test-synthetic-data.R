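test_that("genome simulation is deterministic under a fixed seed and differs across seeds", {
    p <- simParams(genomeLength = 50000, nGenes = 2, seed = 1)
    g1 <- simulateGenome(p)
    g2 <- simulateGenome(p)
    expect_identical(as.character(chromSequences(g1)),
                     as.character(chromSequences(g2)))
    expect_identical(geneRanges(g1), geneRanges(g2))
    expect_identical(repeatRanges(g1), repeatRanges(g2))

    g3 <- simulateGenome(simParams(genomeLength = 50000, nGenes = 2, seed = 2))
    expect_false(identical(as.character(chromSequences(g1)),
                           as.character(chromSequences(g3))))
})

test_that("genome simulation rejects a CDS request larger than the genome", {
    expect_error(simulateGenome(simParams(genomeLength = 5000, nGenes = 4,
                                          cdsLength = 900)),
                 "genomeLength")
    expect_error(simParams(baseErrorRate = 2), "baseErrorRate")
    expect_error(simParams(artifactFrequencyRange = c(0.9, 2)),
                 "artifactFrequencyRange")
})

test_that("genome invariants hold: unique chromosomes, in-bounds CDS, frame", {
    g <- simulateGenome(simParams(seed = 5))
    expect_true(validObject(g))
    cdslen <- tapply(width(geneRanges(g)), mcols(geneRanges(g))$gene_id, sum)
    expect_true(all(cdslen %% 3 == 0))
    expect_true(any(mcols(geneRanges(g))$is_causal))
})

test_that("a mutant line carries exactly one causal nonsynonymous SNP", {
    p <- simParams(genomeLength = 50000, nGenes = 2, nInducedSnps = 1, seed = 3)
    g <- simulateGenome(p)
    line <- simulateMutantLine(g, p, seed = 11)
    expect_equal(nrow(inducedSnps(line)), 1L)
    cs <- causalSnp(line)
    expect_true(cs$causal)
    eff <- annotateVariant(cs$chrom, cs$pos, cs$ref, cs$alt, g)
    expect_equal(eff$category, "nonsynonymous")
    expect_true(mcols(geneRanges(g))$is_causal[
        match(eff$gene_id, mcols(geneRanges(g))$gene_id)])
})

test_that("a pure-transition spectrum forces every non-causal SNP to G>A or C>T", {
    p <- simParams(genomeLength = 50000, nGenes = 2, nInducedSnps = 30,
                   emsTransitionFraction = 1, seed = 7)
    g <- simulateGenome(p)
    line <- simulateMutantLine(g, p, seed = 13)
    s <- inducedSnps(line)
    s <- s[!s$causal, ]
    expect_true(all((s$ref == "G" & s$alt == "A") |
                    (s$ref == "C" & s$alt == "T")))
})

test_that("independent lines rarely share non-causal SNP positions", {
    p <- simParams(genomeLength = 100000, nChromosomes = 1, nGenes = 2,
                   nInducedSnps = 20, seed = 1)
    g <- simulateGenome(p)
    collisions <- 0L
    pairs <- 0L
    for (s in 1:20) {
        l1 <- simulateMutantLine(g, p, "a", seed = 1000 + s)
        l2 <- simulateMutantLine(g, p, "b", seed = 2000 + s)
        k1 <- with(inducedSnps(l1)[!inducedSnps(l1)$causal, ],
                   paste(chrom, pos))
        k2 <- with(inducedSnps(l2)[!inducedSnps(l2)$causal, ],
                   paste(chrom, pos))
        collisions <- collisions + length(intersect(k1, k2))
        pairs <- pairs + 1L
    }
    # expected collisions per pair < n^2 / genome_length = 400 / 1e5
    expect_lt(collisions / pairs, 0.1)
})

test_that("F2 causal genotypes follow Mendelian 1:2:1 expectations", {
    p <- simParams(genomeLength = 30000, nGenes = 1, nInducedSnps = 2,
                   nF2 = 455, seed = 1)
    g <- simulateGenome(p)
    line <- simulateMutantLine(g, p, seed = 5)
    counts <- c(0, 0, 0)
    reps <- 200L
    for (s in seq_len(reps)) {
        coh <- simulateF2(g, line, p, seed = 5000 + s)
        counts <- counts + tabulate(causalGenotypes(coh) + 1L, 3L)
        if (s == 1L) {
            # phenotype is the deterministic map of dosage
            expect_identical(as.character(phenotypes(coh)),
                c("light", "dark", "very_pale")[causalGenotypes(coh) + 1L])
        }
    }
    n <- sum(counts)
    freqs <- counts / n
    se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
    expect_true(all(abs(freqs - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("marker co-inheritance respects the recombination fraction", {
    p <- simParams(genomeLength = 30000, nGenes = 1, nInducedSnps = 3,
                   nF2 = 400, seed = 2)
    g <- simulateGenome(p)
    line <- simulateMutantLine(g, p, seed = 6)
    # r = 0: marker dosage identical to causal dosage in every individual
    coh0 <- simulateF2(g, line, p, markerR = 0, seed = 21)
    for (j in seq_len(ncol(markerDosage(coh0))))
        expect_identical(markerDosage(coh0)[, j], causalGenotypes(coh0))
    # r = 0.5: marker mutant-allele frequency among -/- individuals ~ 0.5
    coh5 <- simulateF2(g, simulateMutantLine(g, simParams(genomeLength = 30000,
        nGenes = 1, nInducedSnps = 10, seed = 2), seed = 6),
        simParams(genomeLength = 30000, nGenes = 1, nInducedSnps = 10,
                  nF2 = 2000, seed = 2), markerR = 0.5, seed = 22)
    hom <- causalGenotypes(coh5) == 2L
    f <- mean(markerDosage(coh5)[hom, ]) / 2
    expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / (2 * sum(hom) * 9)))
})

test_that("pooled sequencing of homozygotes reports the causal SNP at frequency 1 without error", {
    p <- simParams(genomeLength = 30000, nGenes = 1, nInducedSnps = 5,
                   nF2 = 455, poolSize = 96, baseErrorRate = 0, seed = 3)
    g <- simulateGenome(p)
    line <- simulateMutantLine(g, p, seed = 8)
    coh <- simulateF2(g, line, p, seed = 31)
    prof <- poolAndSequence(coh, line, p, seed = 32)
    cs <- causalSnp(line)
    rec <- records(prof)
    hit <- rec[rec$chrom == cs$chrom & rec$pos == cs$pos, ]
    expect_equal(nrow(hit), 1L)
    expect_identical(hit$frequency, 1)
    expect_identical(hit$alt_count, hit$depth)
    expect_true(all(rec$depth > 0))   # zero-depth sites omitted
})

test_that("pooling fails loudly when too few selected individuals exist", {
    p <- simParams(genomeLength = 30000, nGenes = 1, nInducedSnps = 2,
                   nF2 = 20, poolSize = 96, seed = 4)
    g <- simulateGenome(p)
    line <- simulateMutantLine(g, p, seed = 9)
    coh <- simulateF2(g, line, p, seed = 41)
    expect_error(poolAndSequence(coh, line, p, seed = 42), "shortfall")
})

test_that("pool frequency of a marker recovers 1 - r (closed form)", {
    p <- simParams(genomeLength = 30000, nGenes = 1, nInducedSnps = 6,
                   nF2 = 455, poolSize = 96, baseErrorRate = 0,
                   meanDepth = 150, seed = 5)
    g <- simulateGenome(p)
    line <- simulateMutantLine(g, p, seed = 10)
    for (r in c(0, 0.05, 0.1, 0.25, 0.5)) {
        altSum <- depSum <- 0
        for (s in 1:30) {
            coh <- cohortWithPool(g, line, p, markerR = r, seed = 6000 + s)
            prof <- poolAndSequence(coh, line, p, seed = 7000 + s)
            rec <- records(prof)
            cs <- causalSnp(line)
            mk <- rec[!(rec$chrom == cs$chrom & rec$pos == cs$pos), ]
            altSum <- altSum + sum(mk$alt_count)
            depSum <- depSum + sum(mk$depth)
        }
        fhat <- altSum / depSum
        se <- sqrt((1 - r) * r / depSum) + 1 / sqrt(4 * 96 * 30 * 5)
        expect_lt(abs(fhat - (1 - r)), 3 * max(se, 0.004))
    }
})

test_that("artifact injection adds identical keys to every profile", {
    sc <- defaultScenario()
    arts <- sc$artifacts
    expect_equal(nrow(arts), 100L)
    for (prof in sc$profiles) {
        rec <- records(prof)
        keys <- paste(rec$chrom, rec$pos, rec$ref, rec$alt)
        expect_true(all(paste(arts$chrom, arts$pos, arts$ref, arts$alt) %in%
                        keys))
    }
    # injection with zero artifacts is the identity
    p0 <- simParams(nArtifactSnps = 0)
    profs <- list(makeProfile("a", "chr1", 1:3), makeProfile("b", "chr1", 4:6))
    out <- injectArtifacts(profs, sc$genome, p0)
    expect_identical(records(out[[1]]), records(profs[[1]]))
    expect_error(injectArtifacts(profs[1], sc$genome, p0), "two profiles")
})

test_that("all-highdepth artifacts are removed by the depth filter alone", {
    p <- simParams(genomeLength = 50000, nGenes = 2, nInducedSnps = 5,
                   nArtifactSnps = 40, artifactHighdepthFraction = 1,
                   seed = 6)
    g <- simulateGenome(p)
    profs <- list(makeProfile("a", "chr1", 101:105),
                  makeProfile("b", "chr1", 201:205))
    out <- injectArtifacts(profs, g, p, seed = 61)
    arts <- attr(out, "artifacts")
    filtered <- filterByDepth(out[[1]], 200)
    keys <- with(records(filtered), paste(chrom, pos))
    expect_false(any(paste(arts$chrom, arts$pos) %in% keys))
    expect_equal(nrow(records(filtered)), 5L)
})

test_that("the invented color-intensity toy is maximal in the heterozygote", {
    i <- colorIntensity(c(0, 0.5, 1))
    expect_gt(i[2], i[3])
    expect_gt(i[3], i[1])
})
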