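---
title: "Mapping EMS-induced mutations by pooled-segregant sequencing: models and design choices"
author: "bsaMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EMS-induced mutations by pooled-segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaMap)
```

# The mapping model

A single recessive causal locus segregates 1:2:1 in an F2 population
derived from crossing a mutagenized line back to its progenitor.
Phenotype is taken to be a deterministic function of the causal genotype
(`+/+` light, `+/-` dark, `-/-` very pale — the heterozygote-darkest,
overdominant pattern the motivating screen produced).  Pooling `k`
phenotype-selected homozygous mutants and sequencing the pool measures,
at every polymorphic site, the frequency of the mutant-line allele among
`2k` chromosomes:

* at the causal SNP the expected pool frequency is 1;
* at a marker with recombination fraction `r` to the causal locus, each
  pooled gamete carries the mutant allele with probability `1 - r`, so the
  expected pool frequency is `1 - r`;
* at unlinked sites (`r = 0.5`) the expectation is 0.5.

This is what makes the frequency filter work: with a cutoff of 0.95 only
the causal SNP, markers within `r < 0.05`, and artifacts survive.

## The synthetic-data generator

Because the original raw reads are not needed to exercise any of this
logic, the generator produces data directly at the site level, with the
statistical structure the pipeline assumes:

* **Genome** (`simulateGenome`): uniform-random chromosome sequences (2 ×
  100 kb by default), two-exon genes with in-frame CDS (4 genes × 900 bp
  by default, the first flagged causal), and repeat-flagged intergenic
  intervals.  The gene sequences are random, so they may contain internal
  stop codons; the annotation machinery treats stop gain/loss as a
  drastic replacement, and nothing downstream requires open reading
  frames.
* **Mutant lines** (`simulateMutantLine`): 50 induced SNPs by default.
  The causal SNP is drawn from the causal gene's CDS among substitutions
  that are nonsynonymous *and* nonconservative (negative BLOSUM62 score),
  emulating the drastic loss-of-function replacement the screen
  recovered; EMS-type changes (G→A / C→T) are preferred when available.
  Background SNPs are uniform over the genome; a fraction
  `emsTransitionFraction` (default 0.99, canonical EMS chemistry) are
  G:C→A:T transitions drawn at G/C sites.
* **F2 cohorts** (`simulateF2`): two independent gametes per individual;
  each gamete carries the mutant causal allele with probability 1/2 and
  co-transmits each marker with probability `1 - r`, one independent
  recombination event per marker and gamete (no interference — the
  pipeline consumes only per-site frequencies, so linkage *between*
  markers is irrelevant).  Same-chromosome `r` comes from physical
  distance through a Haldane map at 5 cM/Mb (a typical plant euchromatic
  density); different-chromosome markers get `r = 0.5`.  `markerR`
  overrides the map for controlled experiments.
* **Pooled sequencing** (`poolAndSequence`): per-site depth is negative
  binomial (mean 100, size 5) — overdispersed coverage is the norm in
  short-read data and properly exercises the depth filter; the
  alternate-read count is binomial with success probability
  `p(1-e) + (1-p)e`, a symmetric per-read allele flip at `e = 0.001`.
  Zero-depth sites are omitted, as a variant caller would.  The true
  depth distribution and error behaviour of the original commercial
  caller are unknown; this count model is an assumption and is stated as
  such.
* **Artifacts** (`injectArtifacts`): `nArtifactSnps` (default 100) records
  added at identical positions and alleles to *every* profile — the
  signature of assembly error and nonspecific mapping — with frequencies
  uniform in [0.9, 1], positions preferentially (80 %) inside repeat
  intervals, and 30 % given depth uniform in (200, 1000], the
  collapsed-repeat analogs that the depth filter alone removes.

Default cohort and pool sizes (455, 96), depth (100×) and filter cutoffs
(0.95, 200) are the motivating study's design values.  What the
generator does *not* emulate: read-level errors and mapping (we skip
FASTQ entirely), EMS mutation clustering, chromosome-scale recombination
maps, segregation distortion, and variant-caller idiosyncrasies.  Tests
passing on synthetic data therefore validate the *logic* of the pipeline
— set algebra, boundary semantics, closed-form frequencies — not the
behaviour of any particular caller on real reads.

# The candidate-identification pipeline

`runPipeline` applies, in order, with every stage's survivor count kept
in the report:

1. **Frequency filter**: retain records with frequency **strictly**
   greater than `minFrequency` (default 0.95) — the strict reading of
   "> 95 %".
2. **Depth filter**: discard records with depth **strictly** greater than
   `maxDepth` (default 200).  The two published phrasings ("< 200" kept
   vs "> 200 discarded") disagree at exactly 200; we resolve the boundary
   in favour of keeping, treating the discard rule as the operational
   sentence.  Both cutoffs are configurable.
3. **Sequential subtraction**: for each sibling profile in order, remove
   focal records whose key appears in it.  Two deliberate choices:
   * *Match key* (`matchMode`): default `position_and_allele`, because two
     EMS lines can hit the same position with different substitutions and
     only identical calls should cancel; `position_only` is provided since
     the matching rule of the original ad-hoc script is unknowable.
   * *Sibling profiles are used unfiltered*: an artifact may show a
     different frequency or depth in another line, and any presence of the
     key contradicts "unique to the focal line" — the conservative
     reading.

The final candidate *set* is order-invariant (subtraction is set
difference against a union); only the intermediate audit counts depend on
the ordering.  Frequency is always recomputed from `AO/DP` when both are
present in a VCF; `AF` is a fallback.

## Annotation and ranking

CDS positions are mapped to codons respecting strand and exon order,
translated with the standard genetic code, and classified as synonymous
or nonsynonymous (`aa_change` in protein coordinates, codon 1 = CDS
start).  Replacement severity is operationalized as the BLOSUM62 pair
score: negative ⇒ nonconservative (M→K scores −1; I→L scores +2).  This
is a stated proxy for the qualitative "drastic replacement at a conserved
site" judgement — cross-species conservation itself is *not* computed
(multiple-alignment scoring is out of scope).  Ranking order:
nonsynonymous-nonconservative, nonsynonymous-conservative, synonymous,
noncoding; ties broken by genomic coordinate so reports are reproducible.

## Off-target scan

The RNAi trigger criterion is the longest *exact* contiguous match of the
fragment (either strand) to the genome outside the source locus, passed
when ≤ 16 bp.  The published screen used an alignment search with an
E-value cutoff; exact longest-common-substring is the verifiable core of
"perfectly match … contiguous block" and is what we implement
(binary search over block length, with the source locus hard-masked to
`N`; an independent quadratic oracle backs the tests).

# MS identification arithmetic

All published ion values are unit-resolution, so nominal integer masses
(C = 12, H = 1, O = 16) are the primary scale; a monoisotopic mode exists
for high-resolution data.  The pieces:

* `[M−H]⁻` m/z = nominal mass − 1 (negative-mode electrospray).
* Neutral losses from a residue table (glucuronyl 176, hexosyl 162,
  deoxyhexosyl 146, pentosyl 132, malonyl 86); 445 − 269 = 176 identifies
  the glucuronide→aglycone transition.
* 1,3 retro-Diels-Alder cleavage of the flavanone/flavone C ring
  (O1–C2 and C3–C4 bonds) is encoded as an explicit element partition:
  the A side (ring A + O1 + C4 carbonyl, C7H4O4 for the 5,7-dihydroxy
  A ring) is fixed, the B side is the element-wise remainder, so
  complementarity (A + B = parent) holds by construction.  Formula
  arithmetic is verifiable; drawing bond cleavage on a structure graph
  would be over-engineering here.  For naringenin this yields 151/119;
  for eriodictyol the extra B-ring hydroxyl shifts only the B side
  (neutral 136).  Published spectra report 151/119 from the
  eriodictyol-derived 535 precursor as well; the arithmetic here
  reproduces the naringenin pattern exactly and flags the eriodictyol
  B-side shift rather than resolving that discrepancy.
* `annotateSpectrum` matches peaks by rule precedence: molecular ion
  (both `[M−H]⁻` and the radical anion at the neutral mass, which is how
  a 272 product of a glycoside precursor is recognized as free
  naringenin), then loss of up to two attached residues, then RDA
  fragments; unmatched peaks stay `unassigned` — ambiguous published
  losses (e.g. 180, 136 differences) are deliberately not forced onto
  residues.

# qPCR and segregation

Efficiency comes from the standard dilution-series slope:
`E = 10^(−1/slope)` of CP on log10(concentration) (the study states the
dilution design but not the conversion; this is the field-standard
method).  Relative expression is `E_ref^CP(ref) / E_target^CP(target)`,
exactly as published; replicate CPs are averaged *before* the formula
(the published order is unstated) and a first-order delta-method SE is
attached.  Knockdown is `1 − transgenic/wild-type`, scale-invariant.

Segregation uses the Pearson goodness-of-fit (`chisq.test` against the
ratio-implied proportions, df = classes − 1).  For the motivating
phenotype table 112:235:98 the observed total is 445, so the expected
counts are (111.25, 222.5, 111.25) and χ² = 2.2854 (p = 0.319): the
1:2:1 hypothesis stands.  No multiple-testing correction is applied — a
single-test context.

# Numerical choices and degenerate inputs

* Determinism: every simulator takes an explicit integer seed (defaulting
  to `SimParams@seed`) and a fixed seed reproduces output bit-for-bit;
  derive distinct seeds for sibling lines/cohorts.
* An F2 of 455 leaves the homozygote class short of a 96-pool in ~2 % of
  draws; `poolAndSequence` then fails loudly with the shortfall rather
  than silently pooling fewer — callers decide whether to redraw (the
  acceptance script redraws with the next derived seed, as a study would
  grow a fresh cross).
* Zero-depth sites are dropped, flat standard curves and hydrogen-free
  deprotonation are errors, and profile invariants (`0 ≤ AO ≤ DP`, unique
  keys, frequency = AO/DP) are enforced at construction, so malformed VCF
  input fails at the boundary with a locating diagnostic.
* Test and example problem sizes (200 kb genomes, 30-replicate frequency
  grids, 500-replicate filter-survival runs) were chosen so the entire
  suite completes in about a minute while keeping Monte-Carlo standard
  errors well inside the asserted 3-SE bands.

# Known limitations

* Site-level simulation cannot surface alignment-induced artifacts beyond
  the ones it plants by construction; absolute survivor counts from real
  data (which depend on the aligner and caller) are not reproduced, only
  the structure of the triage.
* Effect annotation covers point substitutions in CDS only — no
  splice-site, UTR, regulatory or indel classes (EMS induces point
  mutations).
* The severity scorer is a substitution-matrix proxy; it does not see
  cross-species conservation.
* `colorIntensity` is an explicitly invented toy illustrating how
  intermediate enzyme dosage can maximize pigment intensity
  (production ∝ 1/(1+κd) falling with dosage, retention
  ∝ (ε+d)/(ε+d+K) rising); it is provided for demonstrations only and no
  kinetic claim is attached to it.

```{r toy}
colorIntensity(c(0, 0.5, 1))   # heterozygote-darkest ordering
```
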