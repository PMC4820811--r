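---
title: "Methods: consensus differential expression, reporter-ion quantification, cross-omics intersection and two-point linkage"
author: "crossomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossomics)
```

This vignette is the package's own account of the statistics it
implements, the choices made where the design was genuinely open, and
what the synthetic-data experiments do and do not establish.

## The study design being modelled

A transcription factor is expressed in a cell line that lacks the
endogenous gene, as a wild-type and as a mutant allele, next to
non-transfected controls — eight biological replicates per condition for
RNA-Seq, and an 8-plex isobaric-label MS experiment with three wild-type,
three mutant and two control channels. Differential expression of the
mutant against the wild type, confirmed in both omics layers, nominates
downstream targets; a parametric linkage scan localizes the disease
locus in families; qPCR and dual-reporter assays validate individual
candidates. The package implements the computational stages of that
design as reusable, testable functions.

## Transcript stage

**Normalization.** RPKM, `10^9 * c / (N * L)`, with `N` the per-sample
total count. RPKM is scale-invariant per sample (doubling a library
changes nothing after normalization) — which has a consequence for
background handling discussed under the generator below.

**Three routes, one consensus.** Detection routes differ in their failure
modes, so the pipeline requires agreement, with identical direction,
from all configured routes:

* `route_subtractive()` — subtract the control-condition mean RPKM from
  each test replicate, clamp at zero, log2 (with a small pseudocount,
  default 0.5 RPKM, since clamped values hit exact zero), and run a
  two-sided pooled-variance t-test, keeping features with `p <= 0.05`
  and at least a 1.5-fold change of the adjusted means. Clamping at zero
  is the conservative reading of "subtract the normalized control":
  negative expression is not interpretable.
* `detect_by_sigma()` — per-feature `log2fc` of mutant over wild-type
  condition means, restricted to *valid comparisons* (both means
  strictly positive — the minimal rule that keeps `log2fc` finite at
  pseudocount zero). The dispersion estimate is the RMS **about zero**,
  `sigma = sqrt(mean(x^2))`: no change is the null hypothesis, so
  deviations are measured from 0, not from the sample mean. The RMS
  about zero always dominates the s.d. about the mean (they coincide
  when the mean is 0); both are reported. Features strictly beyond
  `k * sigma` are flagged; ties at the threshold are not hits, and the
  k = 6 hit set is nested in the k = 3 set by construction. The log2
  fold changes entering sigma are computed from the *unsubtracted*
  condition means: subtracted means form ratios of small differences
  whose log explodes for features close to background, which would
  inflate sigma several-fold and detach the threshold from the
  distribution it is meant to summarize.
* `route_count_test()` — an openly simplified two-step count-based test,
  *not* a DESeq reimplementation: median-of-ratios size factors against
  the geometric-mean reference, a per-gene method-of-moments pooled
  dispersion on normalized counts (`var = mu + d * mu^2`, floored at 0),
  and a Wald test on the log2 fold change via the delta method.
  Step 1 keeps genes with Benjamini–Hochberg `q < 0.05` whose wild-type
  expression is at least 1 log2 unit above the non-transfected control
  ("above background"); step 2 tests mutant vs wild type on the
  survivors only, with BH applied within the surviving set. All-zero
  genes are excluded and reported, not imputed.

Benjamini–Hochberg is used wherever an FDR is called for.

**QC summary.** `qc_summary()` derives, from raw per-sample read
accounting in units of 10^6 reads: % mapped without PCR duplication
(of total reads), % properly paired (of deduplicated mapped reads),
sequenced Mb (properly paired reads × read length of 100 bp — paired
reads counted individually), and approximate transcriptome coverage.
The coverage denominator defaults to 65 Mb: this effective human
transcriptome size is inferred from the structure of published summary
tables of this design (sequenced Mb / coverage ≈ 65 within rounding)
rather than stated anywhere, and is exposed as a parameter. Lane and
combined totals are sums of the raw count columns with the percentage
columns recomputed from the sums; when a published table's total rows
disagree with the sum of its printed per-sample cells (rounding drift),
reproducing the printed totals requires summing the printed lane-total
rows themselves, which is what the acceptance checks do.

## Proteome stage

* `filter_psms()` keeps rows with isolation interference strictly below
  30 % (the convention "< 30 %" is a strict bound), q-value at most 0.01
  (a "1 % FDR cutoff" is conventionally inclusive) and peptide rank 1.
* `aggregate_to_protein()` takes, per protein and channel, the median
  over surviving spectra (even counts average the two central values).
  The median is the right de-noiser for multiplicative spectrum-level
  noise and is insensitive to a single aberrant spectrum.
* `quantile_normalize()` forces the six test channels onto the common
  distribution whose r-th order statistic is the mean of the r-th order
  statistics across channels; ties receive the mean of the values their
  ranks span, and the transform is idempotent. The two control channels
  are carried in the protein matrix but excluded from normalization and
  testing — the comparison is strictly 3 vs 3. Proteins with a missing
  or non-positive aggregated channel value are dropped, not imputed.
* `protein_t_test()` is a two-sided pooled-variance t-test on the log2
  normalized values; a protein with zero variance in both groups and
  equal means gets `p = 1` by convention. `detect_proteins_by_sigma()`
  applies the same s.d.-about-zero threshold as the transcript stage,
  and `cross_platform_concordance()` reports proteins hit on two
  platforms with agreeing (and, separately, conflicting) directions.

**A known limitation worth stating plainly:** quantile normalization is
rank-based, so a protein that occupies the same extreme rank in every
channel — the single most (or least) abundant protein — has its fold
change erased entirely, and effects near the rank extremes are
compressed. This is inherent to the method, not to this implementation.
The synthetic generator therefore plants its effects on mid-abundance
proteins (central 80 % of the abundance distribution), which is also the
realistic case: construct-responsive regulatory targets are not the top
protein of a cell's dynamic range. Tests passing on these fixtures say
nothing about recovering effects planted at the rank extremes, where the
method cannot see them even in principle.

## Cross-omics intersection

`map_ids()` aligns the two identifier spaces (identity mapping over the
intersection by default; explicit mapping tables supported; unmapped ids
are reported, never dropped silently). `intersect_candidates()` keeps
features present in the transcript consensus set and on all (default) or
any proteome platform, with one consistent direction across every
supporting screen — a candidate with conflicting directions is never
reported. The default `all_platforms` mode mirrors the "both protocols"
logic that makes a cross-platform protein call credible.

## Two-point linkage

The state space is the ordered two-locus genotype: a haplotype pairs a
diallelic disease locus with one marker allele, and an individual's
state is (paternal haplotype, maternal haplotype). Founder priors are
Hardy–Weinberg at both loci with linkage equilibrium between them;
transmission picks one parental haplotype per locus, recombining with
probability theta (sex-averaged — a single theta, matching the
convention of two-point parametric scans); penetrance is a probability
of affection given 0/1/2 disease alleles, default `(0, 0, 1)` with
disease allele frequency 0.001 — the fully penetrant recessive model.
Marker allele frequencies must be supplied by the user; estimating them
from a handful of founders is biased, and they are study inputs.

`pedigree_likelihood()` evaluates loopless pedigrees by Elston–Stewart
peeling, implemented as variable elimination with a greedy
minimum-cost-first order; per-individual state spaces are pruned to the
support of penetrance × marker observation, each elimination is
rescaled with the log of the scale accumulated separately, so deep
pedigrees cannot underflow. Pedigrees with consanguinity loops (detected
as matings with a common ancestor) fall back to exhaustive enumeration
over the pruned genotype combinations, refusing looped problems with
more than 10 untyped individuals — an explicit capacity bound rather
than a silent hang. The enumeration engine doubles as the independent
oracle for the peeling engine in the tests (agreement to 1e-10 relative
on randomly generated pedigrees).

`lod_score()` is `log10 L(theta) - log10 L(0.5)`; the default profile
grid is {0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5}. `Z(0.5)` is exactly
zero (identical code path, exact cancellation); an obligate recombinant
gives `Z(0) = -Inf`; data impossible under the model at any theta give a
warning and an all-`NaN` profile rather than a fabricated number.
Closed-form anchors used in the tests: a phase-known double backcross
with n non-recombinant meioses has `Z(0) = n * log10(2)`, and the
likelihood factorizes over the two loci at free recombination.

## Assay quantification

* `delta_delta_ct()`: per record `dCt = Ct_target - Ct_reference`,
  per group `ddCt = mean(dCt) - mean(dCt_calibrator)`, fold
  `2^(-ddCt)`. Dispersion is propagated as the fold range
  `2^-(ddCt ± s.d.)` — the standard presentation when error bars are
  reported without a formula. A Ct above 40 cycles encodes undetected
  expression and is treated as missing, never imputed to 40; an
  undetected calibrator target is an error because the fold is
  undefined. The fold is invariant to a run-wide Ct offset.
* `reporter_normalize()`: luciferase over phosphatase, then relative to
  the control pair; invariant to common rescaling of both channels.
* `percent_positive_fold()`: replicate percentages, ratio of group
  means, pooled t-test; symmetric under group swap.

Where published figures are ambiguous about s.d. versus s.e.m. error
bars, the replicate s.d. is what is propagated and both the per-group
s.d. and n are returned, so either presentation can be derived.

## The synthetic-data generator

The generator is the package's experimental ground: every stage is
tested against data whose truth is known.

* **Counts** are negative binomial, `var = mu + dispersion * mu^2`, on
  lognormal gene baselines (log-scale s.d. 1), with per-sample lognormal
  library-size jitter (s.d. 0.1) — the design does not fix library-size
  variation, so it is a parameter rather than a constant. Defaults:
  2,000 genes, 8 replicates per condition, dispersion 0.05 — which puts
  the realized sigma near 0.23–0.26, the scale real studies of this
  design report.
* **Background.** Genes without a planted effect are the cell's own
  transcripts, present identically in all three conditions; genes in the
  effect table are construct-responsive, present in the control at only
  `background_fraction` (default 0.1) of their wild-type mean, and the
  mutant mean is the wild-type mean times `2^log2_effect`. A single
  global control scaling would be cancelled exactly by any per-sample
  normalization (RPKM or size factors), making background subtraction
  vacuous; the two-class design is what lets the subtraction route and
  the count route's "above background" filter do real work, with the
  unchanged majority pinning the normalization scale.
* **PSM tables**: 1–10 peptides per protein, 1–5 spectra per peptide,
  lognormal per-spectrum ionization efficiency (s.d. 0.5) shared across
  channels, independent lognormal channel noise (s.d. 0.25), planted
  effects applied multiplicatively to the mutant channels at the protein
  level — so median aggregation is the correct de-noiser. Configurable
  fractions of rows exceed the interference, q-value and rank filters
  (defaults 0.1 / 0.03 / 0.02, giving filter retention in the mid-80 %
  range, as real reporter-ion data sets show). Planted baselines come
  from the central 80 % abundance quantiles (see the quantile
  normalization limitation above).
* **Pedigrees** are gene-drop simulations: founder haplotypes from the
  stated frequencies, transmissions recombining with probability theta,
  affection deterministic under the penetrance vector. Recombination
  events are counted so that theta = 0 ("no recombinants") and
  theta = 0.5 (independent transmission) are directly checkable.
* **Ct tables**: Gaussian noise on the Ct scale (the standard qPCR
  assumption), target Ct offset by `-log2(true_fold)` from the
  calibrator.
* Each generator seeds its own RNG stream (offset from the
  configuration seed) and restores the caller's RNG state, so adding
  genes to one simulation never perturbs another.

**What the generator does not emulate** — and hence what green tests do
not establish about real data: GC/length biases and batch effects in
counts; reporter-ion ratio compression from co-isolation (the
interference value is simulated as an annotation, not as an actual
mixing of signals); shared/razor peptides (protein ids are taken as
given); genotyping error and allele-frequency misspecification in
pedigrees; qPCR amplification-efficiency deviations from 2 (no Pfaffl
correction). Performance numbers from the fixtures are statements about
the pipeline's statistics under the stated noise model, not about any
laboratory's data.

## Problem sizes and numerical choices

The test and acceptance fixtures use 2,000 genes × 24 samples with 20
planted effects at ±2 log2 (transcript stage), 500-protein 8-plex tables
(proteome), joint fixtures with 8 both-tier / 6 transcript-only /
6 protein-only planted features, pedigrees of up to ~10 members with
2–4 marker alleles, and 100-seed replications for the scalar assays —
sizes at which the full suite completes in well under a minute per
stage while leaving the asymptotic checks (null calibration at 2 × 10^5
draws, 800-meiosis recombination counts) enough resolution to be
binding.

Numerical conventions collected in one place: strict inequality at
`k * sigma`; strict `< 30` interference vs inclusive `<= 0.01` q-value;
pseudocount 0 with validity masking for the sigma route (a configurable
pseudocount exists for robustness studies) and 0.5 RPKM inside the
subtractive route's log; `p = 1` for degenerate zero-variance t-tests
with equal means; BH within the step-2 survivor set only; size factors
defined up to the geometric-mean reference (all invariants stated
modulo that common factor); log-domain rescaling in peeling;
enumeration capacity bounds that fail loudly; frequency vectors checked
to 1e-9.

## Known limitations

Quantile normalization's rank-extreme blindness (above); the count
route's method-of-moments dispersion is less efficient than a proper
shrinkage estimator at very small replicate numbers (it is aimed at the
8-replicate design); the subtractive route's clamped log2 values are not
t-distributed under the null for features at background, so its type-I
control there is approximate — one reason the pipeline's headline call
is a three-route consensus rather than any single route; linkage is
two-point with a single sex-averaged theta, no liability classes, no
multipoint; identifier mapping is one-to-one and within-species.
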