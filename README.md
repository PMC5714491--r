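# bsaMap

Bulk segregant mapping of chemically induced mutants, with the downstream
analyses such a mapping study needs.

## The problem

A recessive (here, overdominant-looking) flower-color mutant arises in an
EMS mutagenesis screen. Because EMS induces dozens of point mutations per
line, crossing the mutant to the progenitor and sequencing a pool of
phenotype-selected F2 homozygotes localizes the lesion: at the causal locus
every pooled chromosome carries the mutant allele (observed alternate
frequency near 1), while unlinked heterozygous sites sit near 0.5. The
remaining obstacle is artifact: reference assembly errors and collapsed
repeats produce high-frequency SNP calls in *every* line. The pipeline
implemented here is the classic three-step triage:

1. **frequency filter** — keep SNPs with alternate-allele frequency
   strictly > 95 %;
2. **depth filter** — discard SNPs with coverage > 200× (kept at exactly
   200), since excessive depth marks collapsed repeats;
3. **profile subtraction** — sequentially remove every SNP whose key also
   appears in the SNP profile of another, independently mutagenized line;
   a true induced mutation is private to its line, an artifact is shared.

Survivors are annotated against the reference gene models (noncoding /
synonymous / nonsynonymous; replacement severity via a BLOSUM62 score with
nonconservative ⇔ score < 0) and ranked, which in practice singles out the
causal nonsynonymous, drastic replacement.

The package also implements the peripheral analyses of such a study:

- a **synthetic-data generator** (genome, EMS lines, F2 cohorts with
  per-marker recombination fractions, pooled sequencing with
  negative-binomial depth and per-read error, shared artifacts), so the
  whole pipeline is testable without any sequencing download;
- an **RNAi off-target scan**: longest exact contiguous match (either
  strand) of a candidate trigger fragment against the genome outside its
  source locus, passed when ≤ 16 bp;
- **flavonoid MS/MS arithmetic** for negative-mode spectra: deprotonated
  ions ([M−H]⁻ = nominal mass − 1), glycosyl neutral losses (e.g.
  glucuronyl = 176 Da), and 1,3 retro-Diels-Alder C-ring cleavage, which
  for naringenin (C15H12O5, 272 Da) yields the complementary 151 (A-ring)
  and 119 (B-ring) ions;
- **efficiency-corrected qRT-PCR**: standard-curve efficiency
  `E = 10^(−1/slope)` from a cDNA dilution series, relative expression
  `E_ref^CP(ref) / E_target^CP(target)`, knockdown fractions;
- **Mendelian segregation tests**: Pearson goodness-of-fit against a
  1:2:1 (or any) ratio.

## Worked example

```r
library(bsaMap)

params  <- simParams(seed = 42)          # 455 F2, pool of 96, ~100x depth
genome  <- simulateGenome(params)
lines   <- lapply(1:5, function(i)
    simulateMutantLine(genome, params, lineId = paste0("ML", i), seed = 100 + i))
profiles <- lapply(seq_along(lines), function(i) {
    cohort <- simulateF2(genome, lines[[i]], params, seed = 200 + i)
    poolAndSequence(cohort, lines[[i]], params, seed = 300 + i)
})
profiles <- injectArtifacts(profiles, genome, params, seed = 999)

report <- runPipeline(profiles[[1]], profiles[-1], genome = genome)
report
#> CandidateReport for line 'ML1'
#>   stages:
#>     raw                          150
#>     frequency_gt_0.95            63
#>     depth_le_200                 49
#>     minus_ML2                    20
#>     minus_ML3                    20
#>     minus_ML4                    20
#>     minus_ML5                    20
#>   20 candidate(s)
```

The focal line starts with 150 SNP calls (49 induced + 1 causal + 100
shared artifacts). The frequency filter removes loosely linked markers,
the depth filter the collapsed-repeat artifacts, and subtraction of the
four sibling profiles removes the remaining shared artifacts, leaving the
20 line-specific SNPs. The top-ranked candidate is the planted causal
lesion:

```r
head(candidates(report), 3)[, c("chrom", "pos", "category", "aa_change",
                                "conservation", "rank")]
#>   chrom   pos      category aa_change    conservation rank
#> 1  chr1 19578 nonsynonymous      F26V nonconservative    1
#> 2  chr1 18688    synonymous      <NA>             n/a    2
#> 3  chr1  7404     noncoding      <NA>             n/a    3
causalSnp(lines[[1]])
#>   chrom   pos ref alt causal
#> 5  chr1 19578   A   C   TRUE
```

The segregation arithmetic of the motivating F2 phenotype table
(112 light : 235 dark : 98 very pale):

```r
segregationTest(c(112, 235, 98))[c("statistic", "df", "p.value")]
#> $statistic  2.285393
#> $df         2
#> $p.value    0.3189578   # 1:2:1 not rejected
```

And the MS identification arithmetic:

```r
deprotonatedMz("C21H18O11")   # apigenin-7-glucuronide [M-H]-  -> 445
deprotonatedMz("C15H10O5")    # apigenin [M-H]-                -> 269
rdaFragments("C15H12O5")[c("aIonMz", "bIonMz")]   # naringenin -> 151, 119
```

## Vignette

`vignettes/bsa-mapping.Rmd` documents the statistical model behind the
generator, the boundary semantics of the filters, the annotation and
ranking rules, the MS and qPCR arithmetic, and the package's known
limitations.
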