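---
title: "Testing species barriers for inversions and reduced hybrid recombination"
author: "recombinv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing species barriers for inversions and reduced hybrid recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombinv)
```

## The question

When two hybridizing species remain distinct despite gene flow, one
classic explanation is that recombination between them is suppressed —
globally, by genic modifiers, or locally, by chromosomal inversions that
lock co-adapted alleles together in heterokaryotypes. `recombinv`
implements the full analysis chain needed to test this hypothesis with
mapping crosses and structural-variant evidence: estimate recombination
landscapes in each parental species and in hybrids, compare them
statistically, quantify the power of the maps to reveal inversions,
sieve split-read inversion candidates against the maps and
trio-assembly alignments, and ask whether surviving candidates carry
population-genetic signatures of barriers (elevated FST) or of adaptive
introgression (elevated fd).

The package is organized around Lepidopteran biology: female meiosis is
achiasmatic, so every observed crossover is paternal, and paternal
bivalents carry close to one obligate crossover each, giving ~50 cM
chromosomes regardless of physical length.

## The cross model and the simulator

`simulateCross()` generates the data a real cross would: ordered
markers along each chromosome and a paternal phase call (A/B, or N for
missing) per marker per offspring.

* **Obligate single crossover.** Each paternal bivalent receives one
  crossover; each offspring inherits a recombined chromatid with
  probability 1/2. An offspring chromosome therefore carries 0 or 1
  crossover with equal probability, and the expected map length is
  50 cM per chromosome. A Poisson(0.5) alternative is available.
* **Uniform crossover position.** The position is uniform on physical
  length. This is the simplest null consistent with broad-scale rates
  that track chromosome length; real landscapes have structure the
  simulator does not attempt to emulate.
* **Inversions as rejection sampling.** A planted inversion suppresses
  crossovers inside its interval only in heterozygous fathers — in the
  hybrid-backcross design, where the F1 father carries one species'
  arrangement over the other's. A crossover drawn inside a suppressed
  interval is rejected and redrawn with the inversion's suppression
  probability, preserving the obligate count. This emulates
  heterokaryotype crossover suppression without modelling unbalanced
  gametes or double crossovers.
* **Error model.** Genotyping errors are independent symmetric A/B
  flips; missingness is independent. These exist to exercise the
  detector's noise filter, not to reconstruct any particular
  genotyping pipeline.
* **Defaults as study conditions.** The default genome is the 21
  published chromosome lengths (272.6 Mb; `hmelGenome()`), the default
  marker spacing is exponential with mean 115 kb, and the default group
  size is 300 offspring — the approximate scale of the real crosses.

Marker positions anchor both chromosome ends so that the map spans the
physical sequence; without anchoring, the expected map length falls
short of 50 cM by the mean terminal gap and the truth-recovery identity
below would not be exact.

## Crossover detection and map estimation

`detectCrossovers()` calls a crossover at each phase switch
corroborated by at least `minSupport` consecutive informative markers
of the new phase; shorter runs are treated as genotyping error and do
not change the accepted phase; missing calls are skipped, so a
crossover interval can extend across them. Each crossover is localized
to the half-open interval between the last informative marker of the
old phase and the first of the new phase. With `minSupport = 1` the
detector recovers simulated truth exactly on error-free data (a
property the tests assert); the default of 2 suppresses single-marker
flips, the dominant error mode of the simulator. The handling of
switches at chromosome ends is a package choice, documented here, not a
reconstruction of any published filter: a terminal run shorter than
`minSupport` is ignored.

`estimateMap()` converts counts to centiMorgans using the
recombination fraction alone — cM increment = 100 x (offspring with a
crossover in the interval) / n — with no mapping function, appropriate
for fine-scale maps where double crossovers between adjacent markers
are negligible. Crossovers whose localization interval spans several
marker intervals are pro-rated by physical overlap, which makes the
identity *total cM / 100 = mean crossovers per offspring* exact by
construction.

## Windowed rates, bootstrap and the window count

`tileWindows()` emits all full windows (default 1 Mb every 100 kb) plus
one trailing truncated window per chromosome when the last full window
stops short of the chromosome end. This convention reproduces exactly
2,549 windows on the 21 published chromosome lengths, which is why it
was adopted; the truncated window's rate uses its actual span.

`windowRates()` pro-rates each crossover's mass across windows by
overlap fraction, so mass sums to one per crossover over any
non-overlapping tiling — conservation-exact, and insensitive to
marker-gap asymmetry, unlike midpoint assignment (whether the original
analysis pro-rated or double-counted whole intervals is not stated
anywhere we can check; pro-rating is this package's documented choice).
`bootstrapCI()` resamples offspring — not crossovers — with
replacement and reports empirical 2.5/97.5% quantiles.

## Statistical comparisons

Per-offspring per-chromosome crossover counts are discrete with heavy
ties, so chromosome-scale comparisons use a bootstrapped one-tailed
Kolmogorov–Smirnov test (`ksBootOneTailed()`): the statistic is
D+ = max(ECDF_b − ECDF_a), sensitive to stochastic reduction in group
b, and the null is built by redrawing both samples with replacement
from the pooled sample — the standard bootstrap-KS construction, chosen
here because the published procedure names the test but not its
resampling scheme. All resampling p-values carry a +1/(n+1) continuity
correction so p is never exactly zero. Under the null the test's
type-I error at 0.05 sits within [0.03, 0.07] (asserted over 1,000
replicates in the acceptance tests).

Window-scale comparisons (`permutationWindowTest()`) permute group
labels across offspring, each offspring carrying all its crossovers, so
the within-offspring correlation structure is preserved. The default is
two-sided; `tail = "less"` asks specifically whether the non-reference
group is reduced. Multiple testing is controlled with Benjamini–
Hochberg across windows (`bhFdr()`, backed by `stats::p.adjust`);
whether the original analysis applied BH to permutation p-values or
used a pooled permutation FDR is not stated, and BH is this package's
recorded choice. Desk-scale defaults (2,000 permutations, 1,000
bootstrap replicates) keep run times in seconds; the full published
scales (270,000 / 10,000) are plain arguments.

## Detection power for random inversions

An inversion is invisible to a linkage map unless flipping its interval
would reorder the map. The default criterion (`"two_informative"`)
requires at least two markers at distinct cM inside the interval;
markers at identical cM are unordered by the map, so a flip changes
nothing — this mirrors the observation that map gaps cannot exclude
inversions. A looser `"two_markers"` criterion is provided; the
original simulation's exact rule is unpublished, so both modes are
offered and neither is asserted as the original. `powerCurve()` places
random inversions uniformly on the genome (chromosome proportional to
length) and reports the detectable fraction; power is monotone
non-decreasing in inversion size, zero on markerless genomes and one
for chromosome-spanning inversions. Reproducing the published ~98/90/75%
values at 500/250/100 kb would require the original marker coordinates;
on exponential-gap synthetic maps with the same mean spacing, power at
those sizes is lower because exponential gaps are more dispersed than
the real marker spacing, and only the qualitative ordering is claimed.

## The candidate sieve

Raw split-read inversion candidates are noisy. Three pure per-candidate
predicates filter them, in any order (the retained set is the
intersection):

1. **Same-species recombination containment**: a crossover interval of
   the candidate's species entirely inside the candidate refutes it.
   Containment, not overlap — a partially overlapping crossover may
   localize outside the candidate.
2. **Collinear trio-scaffold spanning**: a single same-species
   forward alignment covering the candidate and extending strictly more
   than half the candidate length beyond *both* breakpoints refutes it.
   "Both" is this package's reading of spanning "in either direction";
   `spanMode = "either"` is available. Reverse alignments support, and
   never refute, an inversion. Chained alignments are not combined: the
   refuting scaffold must span in one alignment.
3. **Minimum length**: candidates shorter than 1 kb are rejected
   (strictly — exactly 1,000 bp is kept), because linkage
   disequilibrium at that separation is above background anyway.

Tentative-tier candidates (from a relaxed caller setting for
low-coverage samples) are retained only where they overlap a retained
default-tier candidate from a different sample. Survivors merge into
groups by ≥1 bp overlap (connected components; book-ended intervals do
not merge), and each group is classified: `split_and_trio` (some
species has both split reads and a scaffold with forward and reverse
alignments flanking a breakpoint), `split_one_trio_both` (split reads
in one species only, but inverted scaffolds in both — checked first,
since it is the more specific pattern), else `split_only`. "Near a
contig boundary", where apparent inversions often reflect reference
misassembly, defaults to within 5,000 bp (the source analyses say
"near" without a number); the forward/reverse pairing flank defaults to
10 kb, matching the simulator's clean breakpoints.

## Introgression statistics

Around each candidate, up to 11 windows of the candidate's own length
are laid out — five each side plus the candidate — and windows that
would cross a chromosome end are dropped whole, keeping all windows
comparable in size. Per window:

* **FST**: Hudson-type ratio of averages with sample-size correction,
  num = (p_a−p_b)² − p_a(1−p_a)/(n_a−1) − p_b(1−p_b)/(n_b−1) over
  den = p_a(1−p_b) + p_b(1−p_a). The upstream scripts the original
  analysis delegated to do not print a formula; this estimator is the
  package's recorded choice.
* **dXY**: mean per-site p_a(1−p_b) + p_b(1−p_a); scaled over all
  sites when the total is supplied, otherwise flagged
  "variant-scaled".
* **D and fd**: ABBA = (1−p1)p2p3(1−pO), BABA = p1(1−p2)p3(1−pO);
  fd rescales the ABBA−BABA excess by a maximal donor (pD = max(p2,p3)
  replacing both p2 and p3 in the denominator). fd is an admixture
  proportion estimate and is meaningless where D < 0, so it is
  reported as missing there, never clamped; `fdWindow()` also returns
  the denominator so a sign-preserving ratio can be formed for null
  calibration.

The four-population simulator draws an ancestral frequency per site,
drifts it into two species branches and then into P1, P2 (one branch)
and P3 (the other), with a fraction gamma of P2's sites drawn from the
P3 branch instead; the outgroup is fixed ancestral at 95% of sites.
Frequencies are then binomially sampled at the haplotype counts. This
reproduces the qualitative behaviour the statistics need — fd rising
monotonically with gamma, zero expectation under gamma = 0 — but it is
a site-independent drift model: no linkage, no shared genealogies, no
mutation-rate variation, so passing tests say nothing about haplotype-
scale signals in real data.

## Numerical conventions and degenerate inputs

All on-disk tables are 0-based half-open; GRanges objects are 1-based
closed, with half-open [s, e) stored as [s+1, e] so that `width()`
equals physical length. Duplicate or unordered marker positions are
rejected at load. Zero-variation windows give FST = NA; empty windows
give NA statistics; zero crossovers give flat maps and [0, 0] bootstrap
intervals. All randomness flows from a single integer seed per
simulator call.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: 300–600
offspring per comparison, 1,000 null replicates at 500 bootstrap
samples for the KS calibration, 2,000–4,000 permutations, 2,000 power
placements per size, and 10,000–200,000 simulated sites for the
introgression sweeps. These sizes were chosen so the whole suite
completes in minutes while leaving the Monte-Carlo error well inside
every asserted band; the full published resampling depths remain
available through arguments.

## Known limitations

* Map construction itself (marker ordering, linkage-group assignment)
  is out of scope; markers arrive ordered.
* The crossover-position model is uniform; real landscapes are not.
* The split-read caller and read-level simulation are out of scope;
  candidates arrive as intervals.
* The error model is a stand-in: published genotype-filtering details
  live in unpublished supplementary scripts.
* fd and D are frequency-based; haplotype-based statistics are not
  implemented.
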