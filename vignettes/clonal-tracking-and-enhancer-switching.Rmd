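---
title: "Tracking non-genetic drug resistance: clonal barcodes, enhancer switching and amplicon variants"
author: "clonalswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking non-genetic drug resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages({
  library(clonalswitch)
  library(SummarizedExperiment)
})
```

# Scope

`clonalswitch` packages three computational arms of a study of *stable
non-genetic drug resistance* in a BET-inhibitor-resistant leukaemia
model, together with a synthetic-data module that generates every input
with known ground truth:

1. **Clonal barcode tracking.** Cells carry a heritable semi-random DNA
   barcode; amplicon sequencing across serial methylcellulose
   replatings under drug escalation reveals which clones mount an
   adaptive (resistant) response.
2. **Enhancer switching.** After LSD1 inhibition, new enhancers form
   near drug-responsive survival genes and transcriptional
   coactivators (Brd4) redistribute onto them. The package classifies
   peaks into new / pre-existing / new Pu.1 / new Pu.1 active classes
   from coverage fold changes and links them to responsive genes
   within a TSS window.
3. **Targeted-amplicon variant filtering.** Patient cohort variant
   calls are screened with depth / supporting-read / allele-fraction
   rules, duplicate concordance, and cohort-level exclusions.

The package deliberately consumes *processed* inputs (FASTQ of the
barcode amplicon, peak BED, binned coverage bedGraph, DE tables,
variant tables). Alignment, peak calling and differential-expression
fitting are out of scope: those steps belong to BWA, MACS2 and edgeR
and their outputs are this package's inputs.

# The barcode model

## Library design

A barcode is `nRepeats` (default 6) copies of the degenerate IUPAC
unit `NNSWSNNWSW` (S = G/C, W = A/T, N = any base), i.e. a 60-base
semi-random tag, preceded in every read by the fixed constant region
`CGGATCCTGACCATGTACGATTGACTA`. One repeat unit admits
$4^4 \cdot 2^3 \cdot 2^3 = 16384$ sequences, so the full barcode space
($16384^6 \approx 2\times10^{25}$) vastly exceeds any experiment: a
clone's barcode is effectively unique.

```{r}
patternDiversity("NNSWSNNWSW")
design <- LibraryDesign(librarySize = 1000L)
design
```

## Read filtering

`extractBarcodes()` mirrors a grep-style pipeline. A read is accepted
iff, in order:

* the constant region occurs exactly on the forward strand (an
  optional flag adds reverse-complement search);
* at least 60 bases follow it (else `truncated`);
* those 60 bases match the repeated pattern — which in particular
  excludes any literal `N` base;
* their mean phred quality is at least `meanQualityMin` (default 30).

The quality threshold is *inclusive* (a mean of exactly 30 passes) and
is averaged over the barcode bases only, because the barcode — not the
primer-derived remainder of the read — is the datum being trusted.
The three content filters are independent predicates, so their order
cannot change the accepted set; the rejection *reason* is attributed
in the order above. Accepted barcodes are assigned by exact hash
lookup against the reference library (`mapExact()`), reproducing
exact-match-only alignment: one mismatched base leaves a read
unmapped. No error correction is attempted (nearest-neighbour rescue
is a non-goal; with 60 semi-random bases the risk of mis-assignment
under correction outweighs the count gain).

## Retention analysis and the resistant-clone fraction

Per sample, barcodes are ranked by read proportion and the minimal top
set reaching `cumulativeFraction` (default 90%) of reads is taken;
candidates must additionally have *strictly more than*
`baselineMinCount` (default 20) reads at the baseline time point.
Per-plating sets are then chained: a barcode is retained at plating
$t$ only if it was retained at plating $t-1$, so retained sets are
nested and their sizes non-increasing. The resistant-clone fraction
estimate is $|S_{final}| / |S_1|$ for the drug arm.

Two design points deserve attention:

* **Boundary ties.** When the 90% cut falls inside a group of
  barcodes with exactly equal counts, the default (`tieRule =
  "group"`) includes the whole tied group. A rank cut that splits
  exact ties must order them arbitrarily (e.g. by barcode id), which
  makes the retained set depend on clone labels; the group rule makes
  it a function of the count multiset only, so relabelling barcodes
  cannot change the biology. The splitting behaviour remains
  available as `tieRule = "lexical"`.
* **Strictness.** "Above 20 at baseline" is read strictly
  (`> 20`), and the 90% set is the minimal covering prefix
  (cumulative proportion `>= 0.9`, with a `1e-9` relative epsilon
  against float drift).

Because the cumulative cut and the baseline filter deliberately
discard low-abundance signal, the estimator is biased downward: a
resistant clone that drifts below the top-90% set at any single
plating is lost for good. No correction is applied — the number is
reported as-is and should be read as a lower bound.

# The simulation model

`simulatePlatingTimecourse()` emulates the barcoding experiment: a
pool of `nClones` barcoded clones is carried through weekly platings
in a vehicle (DMSO) arm and a drug-escalation arm. The default
schedule is the study design: platings at 400, 600, 800, 1000 nM,
then 1000 nM held for four further weeks (8 platings), with the
control arm at dose 0 throughout.

* A fraction `clonogenicFraction` (default 0.3) of clones is
  clonogenic — able to re-form colonies at all. Non-clonogenic clones
  carry a residual abundance at the first plating
  (`residualGrowth = 0.25`-fold: aborted colonies persist as dying
  cells in the first harvest) and zero afterwards.
* Among clonogenic clones, `resistantFraction` (default 0.1) are
  resistant. The tolerance model is deterministic: resistant clones
  survive every dose; all others survive doses up to
  `naiveTolerance = 400` nM — the first plating's dose, which
  drug-naive cells tolerate by design of the escalation — and are
  eliminated beyond it. Setting `naiveTolerance = 0` gives the harsher
  variant in which any positive dose requires resistance.
* Surviving clones expand `growthRate = 20`-fold per week with
  per-clone lognormal noise (`growthNoiseSd = 0.5`), and each
  replating bottlenecks the pool to `bottleneckSize = 6e5` cells by a
  multinomial draw, emulating replating a fixed cell number.

The defaults are the study conditions: 3000 barcoded clones plated at
20-fold representation into 6×10^5 cells, weekly escalation, roughly a
third of clones with clonogenic potential and a tenth of those able to
adapt. `emitBarcodeReads()` then writes per-sample FASTQ: each read is
a 0–6 base stagger, the constant region, the clone's barcode
(substitution errors at `errorRate`), and random filler to 110 bp,
with Gaussian phred strings clipped to [2, 41].

**Deterministic mode.** Both the bottleneck and the read sampler
accept `sampling = "expected"`, which propagates expectations instead
of drawing multinomials (`round(n * p)` for reads). Together with
`growthNoiseSd = 0` and `errorRate = 0` this leaves the seeded
Bernoulli clonogenic/resistant flags as the only randomness, and —
because exactly tied clones then stay exactly tied, and the group tie
rule keeps tied groups together — the full pipeline recovers the
simulated ground truth *exactly*: the final retained set equals the
resistant∩clonogenic set and the estimate equals the realized binomial
draw. This is the configuration used by the exact parameter-recovery
tests; under the default stochastic conditions the estimate is
below truth — with the default per-plating growth noise the serial
90% cut typically halves the recovered resistant fraction — as
expected from the stringent filtering. The
deterministic read counts sum only approximately to `readsPerSample`
(any exact-sum rounding would have to split tied clones); exact read
conservation holds in the default multinomial mode and is asserted
there.

```{r}
truth <- simulatePlatingTimecourse(nClones = 300, seed = 1)
truth
table(rowData(truth)[, c("clonogenic", "resistant")])
```

What the simulation does **not** model: PCR chimeras and jackpotting,
indels, position-dependent quality decay, barcode synthesis biases,
graded per-clone dose-response curves, or any in-vivo compartment.
Passing tests on this generator therefore certify the *pipeline
algebra* (extraction, filtering, retention logic), not robustness to
every real-world artifact.

# Enhancer switching

## Classification rules

Given binned coverage (`CoverageTrack`: a disjoint GRanges of
fixed-width bins with a score and a library size), the fold change of
a peak between conditions is

$$\mathrm{fold} = \frac{\bar c_{after} + pc}{\bar c_{before} + pc}$$

where $\bar c$ is the mean coverage over the peak interval, scaled
per-million of library size when `normalize = TRUE` (default — the
study compares ChIP coverage across conditions, and depth differences
would otherwise masquerade as biology; `normalize = FALSE` reproduces
raw-ratio behaviour) and `pseudocount = 1` stabilises folds at low
coverage. Classes, all using the same strict `> 4`-fold threshold:

* **new**: H3K27ac fold after LSD1i strictly above threshold;
* **pre-existing**: ≥ 1 bp overlap with the before-condition H3K27ac
  peak set;
* **new Pu.1**: Pu.1 occupancy fold above threshold;
* **new Pu.1 active**: both Pu.1 and H3K27ac above threshold.

Class flags are independent and all reported; the primary label takes
the most specific (`new_pu1_active` > `new_pu1` > `new` >
`pre_existing`), and a peak with no responsive gene within the window
is `unlinked` regardless of folds.

## Gene linking

A peak is linked to every drug-responsive gene (down-regulated more
than 1.5-fold with p < 0.01, both strict; the significance column is
selectable between raw p and FDR, defaulting to raw p) whose TSS lies
within 50 kb of the peak summit, inclusive. Distances are measured
summit-to-TSS because displays and metaprofiles centre on summits; an
edge-to-TSS mode exists for peak-width-insensitive linking. Genes are
single-TSS: multi-TSS inputs are resolved to the 5'-most per strand.

`metaprofile()` averages coverage in `nBins` bins across
summit ± 5 kb windows; window bins that fall off the covered span are
`NA` and excluded from column means, so edge-truncated sites do not
drag averages down. `redistributionScore()` summarises per-site log2
occupancy changes at two site classes and reports the contrast
`mean(Δ new) − mean(Δ pre-existing)`; with pseudocount 0 the
library-size normalisation shifts both class means equally, so the
contrast is normalisation-free.

## The genomic fixture

`generateGenomicFixture()` plants each class by construction on one
synthetic contig: genes every 100 kb (alternate genes responsive),
peaks at class-specific offsets from responsive TSSs, triangular
coverage bumps on a flat background, and planted gains implemented by
*multiplying* the peak's bins between conditions — so the intended
fold holds exactly, independent of bin alignment. `unlinked` peaks sit
in a gene desert ≥ 150 kb from every TSS; Brd4 is doubled at new and
halved at pre-existing peaks, making the expected redistribution
contrast exactly 2 log2 units. With planted folds at twice the
threshold and background at 1, the classifier must recover the
planted labels with precision = recall = 1; this is asserted, as is
agreement of the linker with a brute-force all-pairs distance scan.

```{r}
fx <- generateGenomicFixture(nGenes = 10, nPeaksPerClass = 2, seed = 1)
calls <- classifyEnhancers(fx$peaks, fx$tracks, fx$genes, fx$deTable,
                           preExistingPeaks = fx$beforePeaks)
table(planted = fx$plantedTruth$class, called = calls$class)
```

# Variant filtering

`filterVariants()` applies, in order: per-record retention (depth ≥
20, ≥ 5 supporting reads, VAF *strictly* above 1% — a VAF of exactly
0.01 fails); duplicate concordance (each sample is sequenced in
duplicate to control PCR artifacts; a variant must pass in *both*
replicates, which are then merged with summed depth and mean VAF);
and cohort exclusions on merged records — variants in strictly more
than 50% of distinct samples (recurrent artifacts) or with population
allele frequency strictly above 0.4% are removed. Recurrence is
counted over merged samples, not replicates; a missing population AF
is treated as 0 (absence of evidence in the annotation source is not
evidence of commonness). Annotations are passed through untouched.
Every rejected record carries the first rule it failed, so the reason
table partitions the input.

```{r}
fx <- generateVariantFixture(nSamples = 6, nTrue = 3, seed = 2)
filterVariants(fx$variants)$summary
```

# Numerical and scale choices

* Cumulative-fraction cuts compare against `fraction * total` minus a
  `1e-9` relative epsilon; counts are integers so ties are exact.
* Phred decoding is ASCII−33 throughout; simulated qualities are
  clipped to [2, 41] (Illumina convention).
* BED and bedGraph are 0-based half-open on disk and converted to
  1-based GRanges in memory; default summits are the 0-based midpoint
  of the half-open interval.
* Test and acceptance runs use 1000 clones × 200,000 reads/sample ×
  16 samples for the pipeline-recovery checks and a ~50-gene fixture
  for the enhancer checks — large enough that every rule is exercised
  at cohort scale, small enough to run comfortably on one CPU.

# Known limitations

* The resistant-fraction estimator is a lower bound by construction
  (stringent serial filtering); no statistical correction is offered.
* Exact-match barcode assignment discards reads with any error in the
  60 barcode bases; at realistic error rates a few percent of reads
  are lost, uniformly across clones, so proportions are unbiased.
* The enhancer classifier is thresholding, not inference: no
  multiple-testing control is applied, mirroring the rule-based
  analysis it implements; DE significance is consumed precomputed.
* The in-vivo and patient-derived-xenograft arms of such studies have
  no synthetic counterpart here; they are intentionally unmodelled.
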