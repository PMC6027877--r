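---
title: "Building sex-specific rat genetic maps from heterogeneous stock pedigrees"
author: "hsratmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building sex-specific rat genetic maps from heterogeneous stock pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsratmap)
```

# The problem

A genetic map assigns every genomic position a genetic distance (in
centimorgans, cM) that reflects how often recombination separates it from
its neighbours in one meiosis. Linkage and QTL analyses are computed on
the cM scale, so an inaccurate map moves QTL peaks and distorts their
confidence intervals. The rat long had only a low-resolution map (~1.1 cM,
90 meioses); a modern revision built from a heterogeneous stock (HS)
cohort — 528 rats in 65 families contributing 870 informative meioses,
genotyped at ~95,000 markers — brought the resolution below 0.02 cM and,
for the first time, provided *sex-specific* rat maps (females recombine
~10% more overall: 1,826 vs 1,589 cM, averaged 1,708 cM over 2.6 Gb,
0.66 cM/Mb).

`hsratmap` implements that construction pipeline as reusable, testable
components, together with a cohort simulator whose crossover ground truth
is fully known, so that every stage — genotype QC, recombination-fraction
estimation, map cleaning, resource generation, and QTL re-analysis — can
be validated by parameter recovery rather than by eye.

# The simulator (`makeMarkerPanel`, `buildHSPedigree`, `simulateCohort`)

The generative model is deliberately the exact inverse of the estimator's
assumptions:

* **Pedigree.** Families each have one sire and one dam (founders) and a
  batch of final-generation offspring; 65 families with on average
  870/2/65 ≈ 6.7 offspring give exactly 870 meioses (two per offspring).
  How the original 870 meioses arose from 528 rats is not recorded in the
  published cohort description, so the simulator exposes the counts as
  explicit knobs rather than guessing a deeper pedigree.
* **Founders.** Eight inbred strains, each a single haplotype (inbreeding
  makes the two copies identical). A configurable fraction of markers is
  polymorphic across strains (default 0.9; the monomorphic remainder
  exercises QC). Parent haplotypes are two-strain mosaics: each is one
  simulated meiosis over a random strain pair, which gives parents
  realistic heterozygosity (~45% of markers) without modelling the full
  HS breeding history. Linkage disequilibrium among founders beyond the
  inbred-haplotype structure is *not* modelled.
* **Crossovers.** Counts per chromosome are Poisson(total cM/100) with
  positions uniform on the cM scale (no interference, no obligate
  chiasma), mapped to bp through the inverse of a piecewise-linear truth
  landscape. This is exactly Haldane's model, which makes Haldane-based
  estimation asymptotically unbiased — a deliberate choice so that
  estimator bias can be measured cleanly. The default truth uses the
  published per-chromosome male/female lengths and rn6 physical sizes
  (`ratMapSummary()`, `ratTrueMap()`); a sinusoidal-rate variant exists
  for testing local-rate recovery. The X is simulated as an autosome: the
  published male X length is not explainable by hemizygous transmission
  and we do not attempt to reproduce its mechanism.
* **Noise.** Genotyping error is a symmetric per-allele flip applied per
  call (default 0.002); a configurable fraction of markers (default 1%)
  instead gets a high error rate (15%) to plant the
  high-Mendelian-error markers that QC must catch; calls go missing
  independently (default 2%). `corruptMarkerPositions()` moves a
  minority of markers ≥ a configurable distance to emulate assembly
  misplacements ("errant" markers).

What passing tests on these cohorts do *not* show: robustness to
crossover interference, LD structure among founders, batch effects, or
allele-frequency-dependent error — real-data features outside the
generative model.

# Genotype QC (`runQc`)

Three stages, with the inequalities exactly as in the published
protocol: monomorphic markers (including all-missing ones) are dropped;
markers whose cohort Mendelian-error rate — trio-incompatible offspring
calls over complete trios — exceeds 2% (strict) are removed; the panel is
thinned to the first marker with MAF > 0.05 (strict) per 10-kb window
anchored at bp 1. MAF uses all genotyped individuals, founders included.
A useful scale effect worth knowing: a single miscalled parent produces a
*burst* of Mendelian errors (up to half its sibship), so per-marker error
rates are burstier than a binomial; at 435 trios a one-parent burst
(~0.8%) sits safely below the 2% threshold, which is part of why the
threshold works at the study's scale.

# Map estimation (`estimateMap`)

Markers stay in physical order throughout (the rn6 order is taken as
given; no re-ordering is attempted). The stages:

1. **Parental-genotype inference** (`callParents`): missing parental
   calls are imputed only when a single genotype is compatible with the
   mate and all offspring; contradictions are flagged, never "fixed".
2. **Segregation-distortion filter** (`distortionFilter`): offspring
   counts pooled by mating type are tested against Mendelian ratios with
   a Pearson chi-square (zero-expectation cells pooled); p < 0.001
   removes the marker. The threshold mirrors the documented tolerance of
   the linkage software used for the original map and is configurable.
3. **Phasing and transmission extraction** (`phaseAndExtract`). For each
   parent, transmitted alleles are determined directly where possible;
   double-heterozygous cases are resolved through the mate's phased
   haplotype flow (the offspring's other gamete is known whenever the
   mate's transmitted haplotype agrees on both flanks, and only across
   short flow gaps — long gaps ride on weakly supported stretches of the
   mate's phase, where a single local phase error would corrupt whole
   blocks of resolved transmissions). The relative
   phase of consecutive heterozygous markers is then chosen to minimize
   the total number of recombination events across the parent's meioses.
   This minimization is solved *exactly* by a dynamic program over
   meiosis states (one bit per offspring; compiled code), because the
   classical greedy chain both absorbs real crossovers seen in a single
   sibling and leaves frame-flip local optima that fake coherent
   crossovers in every sibling.
4. **Error hygiene.** Four data-driven screens, all operating on the
   transmitted-haplotype tracks and none using simulation truth:
   unanimous-transmission markers (≥4 informative meioses, all the same
   allele) are treated as miscalled heterozygotes of that parent;
   apparent double crossovers confined to ≤2 informative markers are
   masked as genotyping errors (a real double exchange within ~0.3 Mb is
   vanishingly rare at this density); windows where ≥3 of a parent's
   meioses "recombine" together are repaired as phase artefacts
   (independent meioses essentially never co-recombine); and the first
   and last informative entry of every phase segment is trimmed, because
   a corrupted terminal call cannot be recognized as an isolated flip.
   Without these screens a 0.2% per-call error rate inflates the genome
   map several-fold — each undetected error fakes two recombinants.
5. **Discordant markers.** A marker whose cohort-wide isolated-flip rate
   exceeds `flipRateMax` (default 0.03, with ≥3 flips over ≥10
   informative triples) behaves as if it were genetically somewhere else
   — the signature of a physically misplaced marker. Such markers are
   excluded from the backbone entirely (extraction is re-run without
   them) and are instead *positioned* at their direct recombination
   distance from the nearest backbone neighbour, so that one errant
   marker cannot step the whole downstream map, while the residual
   filter still sees its full displacement.
6. **Interval estimates** (`intervalRecFrac`). For every adjacent-marker
   interval, r = k/n over the meioses of one transmitting-parent sex.
   By default every consecutive pair of informative markers of a meiosis
   contributes to all the intervals it spans (n on each, recombination
   events attributed fractionally by physical width). This bracketing
   attribution uses essentially all 435 meioses per sex on every
   interval; restricting informativeness to meioses heterozygous at both
   immediate flanks (`spanning = FALSE`, also available) leaves n ≈ 200
   and roughly doubles the standard deviation of the genome total, which
   at 870 meioses is the difference between ~0.8% and ~1.7% — the former
   is needed to recover totals within 2.5% reliably.
7. **Assembly** (`assembleMap`): cumulative sums from 0 at each
   chromosome's first marker, Haldane by default (matching the
   generative model; Kosambi available), averaged track = arithmetic
   mean of the sex tracks (the convention consistent with the published
   table arithmetic, e.g. (134.4 + 146.0)/2 = 140.2 for chr1).
   Uninformative intervals carry 0 cM and a flag; they are later bridged
   by the spline. Replicates, when requested, are family-level
   bootstraps averaged per marker with an isotonic pass
   (`replicateConsensus`); the original analysis ran ten replicate
   estimations whose construction is not further described, so the
   bootstrap is our interpretation and is off by default.

# Map cleaning (`cleanMap`)

Two stages, following the published protocol. First, a locally weighted
linear regression of cM on bp per chromosome and sex track; markers with
|residual| > 1 cM (strict; the unit is presumed cM, the published text
does not state it) are removed from all tracks. Two settings are ours
where the protocol is silent, chosen for robustness rather than taken
from the original: the fit uses Tukey-biweight robustness iterations,
because the errant markers being hunted are exactly the outliers that
would otherwise bend a non-robust reference curve (measured on simulated
cohorts with 5% displaced markers, a non-robust fit removes over half of
the *clean* markers; the robust fit removes <1%); and the default span
is 0.05 of the chromosome's markers (≥25), small enough that the random
walk of cumulative sampling noise does not masquerade as residuals.
Second, a Fritsch–Carlson monotone shape-preserving cubic interpolant is
fitted through the retained anchors per track (ties in bp collapsed to
mean cM, residual non-monotonicities resolved by isotonic projection) —
an interpolating, not smoothing, spline, so every retained anchor is
reproduced exactly and the derivative (the local recombination rate,
cM/Mb) is continuous and non-negative. Beyond the terminal anchors the
model extends at the terminal segment's slope, clamped at cM ≥ 0, and
flags the extrapolation.

# Resources (`kbGrid`, `annotateMarkers`, `summarizeMap`)

The model is evaluated at every kilobase per chromosome, and arbitrary
marker lists (e.g. SSLP panels) are annotated with all three cM tracks;
markers with no position or several reported positions are flagged
`unmapped` and given no cM, as in the published resource. Chromosome
summaries round cM to one decimal and rates to two, as in the published
table; the genome-wide headline rate is the *unweighted mean* of the
per-chromosome rates — the convention that reproduces the published 0.66
(revised) and 0.65 (historical) figures, which the ratio of the printed
totals does not (both conventions are reported). Average map resolution
is total averaged cM over the marker count.

# QTL machinery (`scanQtl`, `compareScans`)

Single-locus F2 interval mapping by multiple imputation: genotypes on a
2-cM grid (united with the typed markers) are drawn from their joint
distribution given flanking markers under a Markov model with Haldane
recombination probabilities and zero genotyping error; per imputation
LOD = (n/2)·log10(RSS0/RSS1) comparing covariates+additive+dominance
against covariates only; imputations combine as log10 of the mean of
10^LOD (128 draws by default). Genome-wide significance uses permutation
of the phenotype (1,000 by default; 0.05 significant, 0.63 suggestive,
quantiles of the per-permutation genome-wide maximum). Permutation scans
default to 16 imputations: the null maximum statistic is insensitive to
the imputation count, and this keeps 1,000 permutations tractable.
Credible intervals are bayesint-style: the smallest run of consecutive
grid points containing the peak with ≥95% of the 10^LOD mass. Peaks are
per-chromosome grid argmaxes (ties to the lowest cM), "detected" when
above the suggestive threshold; comparisons between scans under two maps
match QTL by scan and chromosome, compute shifts where detected in both,
and flag shifts strictly greater than 10 cM. Applied to the published
old-vs-new peak table this flags 9 of the 32 QTL detected with both maps
(one further QTL is detected only with the old map). The models labelled
A–D in that table are defined in the source cross's own publication, so
the package implements a generic covariate specification rather than
reproducing those fits.

Calibration is density-dependent: on a dense map (markers every 5 cM,
n = 200, additive effect 0.5 SD) the 95% intervals cover the true
location in ~97% of simulations, whereas sparse 10-cM maps show the mild
undercoverage (~88%) known for this interval type. The dense regime is
the one a sub-cM map serves.

# Numerical and interface choices

* Dosage coding 0/1/2 (copies of allele 2), `NA` missing; coordinates
  1-based bp throughout; PED/MAP for genotype interchange (allele
  identities are not part of that dialect — supply a reference-allele
  table for a lossless round-trip); TSV with `#` comments elsewhere.
* `readGeneticMap()` validates cM monotonicity and names offenders;
  in-memory raw maps may legitimately be non-monotone before cleaning.
* All stochastic entry points take explicit seeds; a fixed seed gives
  bit-identical cohorts, maps and scans. `runPipeline()` writes every
  artifact with a manifest of stage parameters, the seed and file
  digests.
* Estimation capping: pooled interval r is capped at 0.499 and direct
  discordant-marker distances at r = 0.45 (≈80 cM) — far beyond any
  plausible adjacent-interval distance but finite, so one unlinked
  marker cannot produce infinities.
* Problem sizes used by the test-suite recovery runs: the full 21-chromosome
  genome at ~2,000 retained markers per chromosome and 870 meioses for
  the headline recovery (about 3–4 minutes); three chromosomes for the
  displaced-marker cleaning check; 200 replicates of a two-chromosome F2
  cross for interval coverage.

# Known limitations

* No crossover interference in the generative model or the estimator;
  with strong interference Haldane distances are biased upward, and
  Kosambi (available) is only a partial remedy.
* The coherent-switch repair assumes independent meioses rarely
  co-recombine within a small window; an extreme real hotspot together
  with few informative meioses could in principle be over-repaired.
* The residual filter removes errant markers; it does not re-position
  them.
* X-chromosome hemizygosity is not modelled (autosomal treatment by
  default; a female-only X map can be obtained by using the female track).
* The two-stage discordance detection doubles the phasing work; on the
  full genome the estimation stage takes a few minutes of a single CPU.
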