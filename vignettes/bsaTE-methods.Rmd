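---
title: "Methods: pooled-bulk ED mapping, LTR-RT presence/absence, and segregation genetics"
author: "bsaTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-bulk ED mapping, LTR-RT presence/absence, and segregation genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(bsaTE)
  library(GenomicRanges)
})
```

# Overview

`bsaTE` implements the computational core of a marker-discovery story
in peach (*Prunus persica*): a dominant promoter insertion of an LTR
retrotransposon travels with the blood-flesh trait in F1 crosses, and
the package provides (i) the pooled-sequencing Euclidean-distance scan
used to map such a locus, (ii) a cross-assembly presence/absence
classifier for intact LTR retrotransposons with twin-LTR insertion
dating, (iii) the Mendelian/co-segregation statistics used to connect
marker genotypes to phenotype classes, and (iv) a seed-deterministic
simulator that generates all of these inputs with known ground truth.
Everything below is the package's own account of the models, the
tunable parameters, and the design decisions behind them.

# The ED bulk-segregant scan

## Model

Two pools of phenotypically extreme F1 individuals (here 15 "mutant" =
blood-flesh and 15 wild-type individuals, each pool sequenced at ~30x)
are compared SNP by SNP.  For each SNP the per-pool base frequency
vectors over A/C/G/T are contrasted with the Euclidean distance

$$ED = \sqrt{(A_m - A_w)^2 + (C_m - C_w)^2 + (G_m - G_w)^2 + (T_m - T_w)^2},$$

which is 0 for identical pools and $\sqrt 2$ for pools fixed for
different bases.  At a locus unlinked to the causal variant the two
pools are random samples of the same population and $ED$ fluctuates
around a small read-sampling value; at the causal locus the selection
of the bulks forces a frequency contrast (0.5 vs 0 under the
heterozygous-carrier x non-carrier cross used here, so
$ED \approx \sqrt{0.5} \approx 0.707$).

$ED$ is raised to the fifth power to sharpen peaks relative to the
noise floor, averaged in 100 kb windows slid by 10 kb (windows are
anchored at position 1 and truncated at the chromosome end), and the
genome-wide empirical 95th percentile of the window statistic is the
screening threshold.  Maximal runs of consecutive supra-threshold
windows are merged into candidate intervals; the top interval is the
one with the largest window statistic.

## Site filtering

Sites enter the scan only if they pass GATK-style annotation bounds:
`DP >= 4`, `QD >= 2.0`, `FS <= 60.0`, `MQ >= 40.0`,
`MQRankSum >= -12.5`, `ReadPosRankSum >= -8.0`.  The depth clause is
deliberately implemented as a *keep* rule (drop low-depth sites):
removing high-depth sites would discard exactly the best-measured
SNPs.  Missing annotations pass by default (simulated tables may not
carry them); `strict = TRUE` inverts that.  The filter is a pure
partition: every input row ends up in `kept` or in `rejected`
together with the list of clauses it failed.

## Numerical choices

* The threshold quantile is `stats::quantile(..., type = 7)` (linear
  interpolation between order statistics) so thresholds are
  reproducible bit for bit; on window statistics $1,\dots,100$ the
  0.95 level gives 95.05.
* Window aggregation defaults to the mean of $ED^5$ (sum available);
  windows with fewer than `minSnps` SNPs carry `NA` and do not enter
  threshold estimation.
* Candidate intervals require *strictly* supra-threshold windows, so
  a degenerate scan in which every window ties at the threshold calls
  no interval.
* Coordinates are 1-based inclusive everywhere inside the package and
  converted to 0-based half-open only when writing BED.

## Why the simulated genome is multi-chromosome

The empirical 95% threshold is meaningful only when windows linked to
the causal locus are a small minority of all windows, which is how a
real genome-wide scan behaves (a few Mb of linked signal out of
~240 Mb).  We verified numerically that a single-chromosome downscale
(one 10 Mb chromosome at 1 cM/Mb) cannot support the recovery
property at all: the whole chromosome lies within ~10 cM of the
causal locus, the plateau of maximal expected contrast spans several
Mb (its width is set by the ~0.3 recombination breakpoints per Mb
carried by the 30 informative bulk haplotypes), and because that
plateau alone exceeds 5% of all windows the threshold always lands
*inside* the plateau's noise distribution.  The supra-threshold run
then fragments into read-noise clumps and the top interval is an
essentially random 100-300 kb piece of the plateau — at any SNP
density.  The simulator's default genome therefore reproduces the
study-scale geometry: 8 chromosomes of 30 Mb (~240 Mb, matching a
peach assembly), with the causal insertion at 3 Mb near the top of
chromosome 5, where the threshold is set by the unlinked background
and the supra-threshold region is one contiguous block around the
causal position.

# The synthetic-data generator

## What it emulates

* **Cross**: an F1 of 120 offspring from a heterozygous carrier of
  the causal insertion x a homozygous non-carrier.  Gametes follow
  Mendelian sampling with Haldane recombination
  ($r = (1 - e^{-2d})/2$, $d$ in Morgans) on a uniform 1 cM/Mb map.
  Every SNP is informative and phase-known with respect to the
  carrier haplotype — the cleanest design for parameter-recovery
  tests, since the expected pool contrast at the causal SNP is then
  exactly 0.5 vs 0.
* **Phenotype**: blood flesh is dominant for presence of the element
  (the study's carrier/non-carrier split is perfectly concordant, so
  a deterministic dominance model is appropriate; it is
  configurable).  The fruit development period (FDP) class follows
  the 9 bp-insertion genotype (9/9 -> 60-90 days, 0/9 -> 90-120,
  0/0 -> 120-150) and is advanced one ordinal class for carriers,
  floored at the earliest class — an ordinal shift, because the data
  being emulated are class reassignments, not day measurements.
* **Pooled depths**: per pool and site, total depth is
  Poisson(30) and base counts are multinomial (sampled as a
  vectorised chain of conditional binomials) around the pool's true
  allele frequency; an optional uniform miscall rate perturbs the
  base composition.  The 30x depth is treated as per pool.  Quality
  annotations are filled with passing values unless a failure
  fraction per clause is requested, which is how the filter's
  behaviour is exercised.
* **SNP density**: one SNP per 2 kb by default.  Real inter-parent
  SNP densities are 10-100x higher; 2 kb is the sparsest density at
  which window read-noise stays small relative to the linkage signal
  while keeping a full 8 x 30 Mb replicate under ~10 s.
* **Genomes with planted elements**: intact elements
  (5' LTR + internal + 3' LTR, 2-7 kb) are inserted with a
  duplicated target site (5 bp by default, a typical LTR-RT TSD) and
  independent per-copy LTR point mutations; a derived target genome
  applies per-element edits (keep / delete with TSD restoration /
  degrade to a target identity / delete the upstream flank), each
  with a known expected classification.

## What it does not emulate

No read-level artefacts (mapping bias, indel errors, duplicated
reads), no partially informative or mis-phased SNPs, no segregation
distortion, no solo-LTR recombinants, and no nested or truncated
elements.  Passing recovery tests therefore demonstrates the
statistics and the bookkeeping, not robustness to alignment artefacts
in real data — real scans should still be inspected per chromosome
(`plotScan()`).

# LTR retrotransposon classification and dating

## Flank anchoring

For each intact element (2000-7000 bp inclusive) the 500 bp flanks
are extracted and located in the target assembly.  The internal
aligner is deliberately simple and fully deterministic: exact 31-mer
seeds taken along the flank propose candidate placements, each
candidate is rescored ungapped at +1/match, -1/mismatch, both
orientations are searched, and a hit is *unique* iff its score
reaches half the flank length and beats the second-best candidate by
at least 10% of the flank length.  The hit contract (best location,
second-best score, uniqueness) is the same shape a BWA-style
mapper's hit table would provide, so external hits can substitute
for real genomes.

Both anchors must be unique, co-linear on one target contig, and at
most 20 kb apart.  The gap $g$ between the anchors' inner ends is the
geometry: $g \le 1$ kb means the element is absent from the target
(the two flanks abut around the single remaining TSD copy) and the
element is query-specific (`INSERTION`); $g$ within +/-20% of the
element length means a copy is present, and the query element is
globally aligned to the spanned target sequence — identity >= 95%
with coverage >= 95% is `HIGH_SHARED`, identity >= 80% with coverage
>= 50% is `LOW_SHARED`, anything poorer is a decayed copy
(`ELIMINATION`).  Any other geometry, a missing flank (< 100 bp after
clipping at contig ends) or unpairable anchors give `UNKNOWN`.  The
identity/coverage boundaries are explicit configuration
(`ltrThresholds()`): the five-way typing is conventional, and 95%/80%
is the customary high/low identity split.

## Insertion age

The two LTRs of an element are identical upon insertion, so their
divergence dates it.  The raw mismatch proportion $d$ is computed
over gap-free columns of a global alignment of the two copies,
corrected as $K = -\tfrac34 \ln(1 - \tfrac43 d)$ (Jukes-Cantor), and
converted to time by $T = K / (2\mu)$ — the factor 2 because both
copies accumulate substitutions.  $d \ge 0.75$ is outside the JC
domain and raises an error.  The substitution rate defaults to
$\mu = 1.5\times10^{-8}$ substitutions/site/year, a commonly used
order of magnitude for plant neutral sites; it is a parameter, it is
echoed in every output, and ages should be read as relative unless
$\mu$ is calibrated for the taxon.

# Segregation genetics

* `expectedOffspringRatio()` reduces the Punnett distribution of a
  single-locus cross to the lowest integer ratio (0/9 x 0/9 ->
  1:2:1; 0/0 x 0/9 -> 1:1).
* `chiSquareGof()` is the Pearson statistic without continuity
  correction, with $E_i = N r_i / \sum r$ and df = classes - 1.  On
  the packaged FDP segregation counts this reproduces the printed
  3.54 (9/31/19 vs 1:2:1, accepted at 5.99) and 50.86 (36/20/0,
  rejected).  The 1:1 rows of the second cross in the same packaged
  table do not reproduce from their printed counts under the Pearson
  statistic with or without Yates correction; those two values are
  treated as non-recomputable rather than silently adjusted, and the
  packaged table retains the counts so the discrepancy is visible.
* `chiSquareCritical()` is the upper-tail chi-square quantile
  (`stats::qchisq`, i.e. the inverse regularised incomplete gamma),
  matching published tables to 2 dp.
* `colorIntensityRule()` encodes the observed three-locus rule for
  blood-flesh intensity: carriers of the promoter element (R1R2)
  map (D1D1,T1T1) -> dark, (D1D2,T1T1) -> blood, (D2D2,T1T1) ->
  light, (D2D2,T1T2) -> none; non-carriers are always "none"; any
  carrier combination outside the observed table returns an explicit
  `"unclassified"` sentinel instead of an extrapolated class.
* `fdpClassify()` bins FDP days as [60,90], (90,120], (120,150] —
  boundary days go to the earlier class, a convention chosen because
  the printed class labels overlap at 90 and 120.
* `carrierRatio()` reports per-group carrier percentages rounded to
  the integer (the precision such tables print) alongside the raw
  value.

# Problem sizes used by the test-suite and the acceptance script

Chosen as desk-scale defaults: 20 scan replicates of the full default
simulation (8 x 30 Mb, 96k SNPs, ~8 s each); 54 planted elements
across two contigs of 200 kb and 160 kb for the classifier
truth-table check; 200 single-marker replicates for the causal-ED
expectation; 1000-SNP instances for the brute-force window oracle.

# Known limitations

* The flank aligner is exact-seeded and ungapped; highly repetitive
  or indel-rich flanks in real assemblies should be anchored with an
  external mapper and fed in through the hit contract.
* The classifier compares one query element against one target
  span; tandem or nested insertions produce `UNKNOWN` geometries
  rather than being resolved.
* The simulator's phase-known, fully informative SNP design is an
  idealisation; real bulk scans carry partially informative markers
  and reference bias that the package does not model.
* Insertion ages inherit the full uncertainty of $\mu$ and of the
  single-alignment estimate of $d$; no confidence intervals are
  attached.
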