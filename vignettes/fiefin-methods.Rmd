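---
title: "Methods: nominal-mass fingerprinting and discriminant modelling with fiefin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nominal-mass fingerprinting and discriminant modelling with fiefin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiefin)
```

## The problem fiefin addresses

Flow infusion electrospray-ionization mass spectrometry (FIE-MS) produces one
composite spectrum per biological sample, with no chromatographic separation.
Metabolite fingerprinting turns such spectra into a samples × integer-m/z
matrix of relative signal abundances and then asks two questions: *can the
sample classes (breeds, diets, cohorts) be told apart*, and *which signals
carry the separation*. fiefin implements that entire workflow — fingerprint
construction, PC-LDA discriminant modelling, bootstrapped random-forest
classification, ensemble feature ranking, correlation clustering of the
selected signals, categorical-metadata association screening, and
accurate-mass adduct/isotopologue annotation — together with a synthetic-data
generator that makes every stage testable without any instrument data.

## Fingerprint construction

A centroided peak list is reduced to integer nominal-mass bins: each peak is
assigned to its nearest integer m/z provided it lies within ±0.1 Da of it
(`bin_peaks()`, tolerance configurable). Peaks with fractional mass in
(0.1, 0.9) are discarded and counted; discarding, rather than forcing an
assignment, is the only reading under which the tolerance does anything. The
window comparison absorbs the binary representation error of decimal peak
positions (e.g. 700.1 − 700 exceeds 0.1 by ~2 × 10⁻¹⁴), which would otherwise
drop exactly-at-boundary peaks.

Acquisitions split over several scan windows (default 15–110, 100–220,
210–510, 500–1200 m/z) are merged onto the union axis; a bin covered by two
windows takes the mean of the contributions (`merge_scan_ranges()`). The
windows are treated as closed integer intervals, making 15..1200 the default
axis with overlap regions 100–110, 210–220 and 500–510. No reconciliation
rule is canonical for such overlaps; the mean is unbiased when both windows
measure the same quantity.

Pre-processing then applies, in order:

1. **Baseline subtraction** (`subtract_baseline()`): per sample, the 5th
   percentile of its positive bin intensities is subtracted everywhere and
   results are floored at zero. A per-sample scalar statistic was chosen over
   instrument blanks (which require extra acquisitions); the quantile is
   configurable.
2. **log10 transform** (`log_transform()`): `log10(x + 1)`, damping the
   heavy-tailed variance of ion counts. The +1 offset keeps exact zeros —
   unavoidable in binned count data — at zero and the map strictly monotone.
3. **TIC normalization** (`tic_normalize()`): each row divided by its sum, so
   bins become relative abundances summing to one and per-sample infusion or
   concentration scale cancels.

State flags on the `fingerprint_matrix` (`binned`, `baseline_subtracted`,
`log_transformed`, `tic_normalized`) gate the legal ordering, so an illegal
sequence (e.g. baseline after log) errors instead of silently distorting
data. The default order applies log10 *before* TIC normalization;
`preprocess_fingerprints(order = "tic-log")` gives the more common
TIC-first variant. The orders are not equivalent: normalizing after the log
divides by the sum of logs, which leaves a shared denominator across bins.
At very low biological noise that shared term dominates per-bin variance and
induces common-mode correlation between unrelated bins — which is why
correlation-cluster analyses (below) are best run on TIC-first-processed
data, and why the switch exists. Positive- and negative-mode spectra are
always processed as separate matrices.

## PC-LDA and the Tw eigenvalue

With p ≫ n, linear discriminant analysis is fitted on principal-component
scores (`pc_lda()`). PCA retains the smallest number of components reaching
95 % cumulative variance (configurable), capped at n − g (g = number of
classes) so the within-class scatter stays invertible. Discriminant axes are
the generalized eigenvectors of the between-class scatter **B** against the
within-class scatter **W**; each axis's eigenvalue Tw = its between/within
scatter ratio is the adequacy metric: **adequate above 2.0, poor below 1.0**,
intermediate otherwise, with strict boundaries (`tw_adequacy()`). The
eigenproblem is solved through the symmetric W^−1/2 B W^−1/2 form; if W is
singular despite the PC cap, a ridge of 10⁻⁸ × trace(W) is added with a
warning. Axes (PCs and DFs) are oriented so their largest-magnitude loading
is positive, making scores reproducible across BLAS implementations. Tests
verify that the DF1 between/within ratio equals Tw to 10⁻⁶, that Tw is
invariant under invertible diagonal rescaling of the variables, and that Tw
rises monotonically with an injected class shift.

## Bootstrapped random-forest classification

Pairwise class separation is scored by `bootstrap_classify()`: each of 100
bootstraps (default) draws a *stratified* 2/3 training / 1/3 test split
(test size = ⌈n_c/3⌉ per class; stratification prevents one-class training
sets at small n), grows a 1000-tree random forest on the training part, and
evaluates the held-out third on three statistics:

- **ACC** — fraction of test samples whose top vote class is correct (vote
  ties resolved toward the lexicographically smaller label);
- **AUC** — rank-based (Mann–Whitney) area under the ROC curve of the
  positive-class vote fractions, ties counted ½;
- **margin** — mean over test samples of (vote fraction for the true class −
  largest vote fraction for any other class), in [−1, 1].

Aggregation over bootstraps is the mean by default (median available); a
model is **adequate** when aggregate margin > 0.2 *and* AUC and/or ACC > 0.8,
all strict (`adequacy()`). One master seed spawns one sub-seed per bootstrap,
so raising `n_bootstraps` extends a report without reshuffling earlier
splits, and identical seeds reproduce reports exactly. The forest itself
comes from the randomForest package; the bootstrap protocol, the three
statistics and the adequacy rule are implemented here and checked against
hand-counted vote matrices and a permutation null (AUC ≈ 0.5).

## Ensemble feature ranking and correlation clustering

`rank_features()` scores every bin by three independent criteria:

- **Importance Score** — out-of-bag permutation importance (unscaled mean
  decrease in accuracy) from a random forest. This is the standard
  realization of "accuracy lost when the feature's information is removed";
  a literal delete-and-retrain comparison is kept as a slow reference oracle
  in the test suite and agrees within estimation noise.
- **per-feature AUC** — rank-based AUC folded to max(AUC, 1 − AUC), so a
  signal consistently *lower* in one class ranks as highly as one
  consistently higher.
- **Student's t-test** — two-sided pooled-variance form (Welch by option),
  ranked by p-value. The degenerate all-constant case returns t = 0, p = 1.

The three rank columns are fused by their mean (`rank_combined`); no fusion
rule is canonical, and the mean treats the rankers symmetrically. A bin is
`selected` when p < 0.05 **and** Importance Score > 0.002. The importance
gate's scale depends on forest configuration, so it is exposed as a tunable
rather than asserted as portable.

`correlation_clusters()` links two selected bins when their Pearson |r|
exceeds 0.7 and reports connected components (largest first, ties by
smallest member bin). Within a fingerprint such components typically collect
ionization products of one metabolite; `interpret_cluster()` labels member
pairs by nominal spacing — Δ16 as an [M+Na]⁺/[M+K]⁺ adduct pair (K − Na =
15.97 u), Δ1 as a ¹³C isotopologue pair. Constant bins have undefined
correlations and become warned singletons.

## Metadata association screening

Before interpreting a per-factor discriminant model, `screen_metadata()`
cross-tabulates every pair of categorical metadata factors and applies
Pearson's χ² test for count data — no continuity correction, asymptotic
p-value, empty categories dropped with a warning, expected counts < 5 warned
but not switched to an exact test. With the seven standard factors (breed,
age category, gender, sexual status, weight category, body condition score,
diet group) there are C(7,2) = 21 pairs and the Bonferroni-adjusted level
maintaining a 5 % family-wise error is 0.05/21 ≈ 0.0024. A flagged pair
(say, breed with weight) warns that a model discriminating one factor may be
confounded by the other.

## Accurate-mass annotation

`adduct_mz()` computes theoretical m/z for +1 cation adducts: monoisotopic
mass + charge-carrier mass − one electron mass + n¹³C × 1.00335 u. The
electron-mass correction (~0.55 mDa) is required: without it, 5-dp
calculated masses are off by about 1 mDa. Atomic masses are full-precision
CODATA/AME monoisotopic values kept in one constants table; truncating them
to 8 decimals shifts rounded 5-dp results at the last digit for ¹³C
isotopologues. `match_candidates()` enumerates all (formula, adduct, ¹³C)
combinations within a ppm tolerance (default 5) of an observed mass, sorted
by |ppm|; ppm is always computed against the theoretical mass. The engine
covers [M+H]⁺, [M+Na]⁺, [M+K]⁺ and single-¹³C isotopologues; fragment
prediction and spectral-library scoring are out of scope.

## The synthetic-data generator

`synthetic_design()` + `generate_fingerprints()` emulate the statistical
structure the analysis assumes, not the chemistry of real plasma:

- per-bin baseline abundances log-uniform over 10³–10⁵ (arbitrary ion
  counts);
- class-specific shifts on designated discriminatory bins, additive on the
  log10 scale (multiplicative noise is what the log10 step is for);
- adduct/isotopologue clusters: satellite bins at +1/+16 m/z generated as
  fixed multiples of an abundant anchor plus 0.01 log10 noise, so pre-noise
  pairwise |r| > 0.9. Anchors draw from the top abundance decade —
  annotated adduct clusters belong to abundant metabolites, and satellites
  of a faint anchor would be floored by the baseline correction;
- per-sample TIC scale factors, log-uniform over 0.5–2, which
  `tic_normalize()` demonstrably removes;
- optional replicate structure: an individual-level latent profile plus
  within-individual noise, emulating repeat sampling of the same animal.

Defaults — 2 classes × 12 individuals, ~250 bins over 15–1200 m/z, noise SD
0.2 log10 units — mirror a two-breed controlled comparison. The generator
does *not* emulate realistic isotope intensity ratios, chemically plausible
m/z distributions, or batch drift; passing recovery tests therefore
demonstrates the statistics of the pipeline, not instrument robustness.
`generate_peaklists()` writes each matrix back out as jittered peak lists
(jitter truncated to ±0.1 Da) so binning round-trips exactly, and
`generate_metadata()` draws categorical tables with one controllably
associated factor pair. All generators are pure functions of
(design, seed).

## Numerical and design choices

- **Problem sizes in checks.** The statistical validation suite runs at
  scaled-down sizes chosen to exercise the mathematics: 10–25 bootstraps of
  50–200 trees for classification checks, 500-tree forests for importance
  ranking (200-tree importance estimates are visibly noise-limited), 40–100
  bins, 20–40 samples, 10–20 seeds per property, 10,000 replicates for
  t-test calibration, and 2,000 for the family-wise-error check.
- **Recovery margins.** With 5 planted bins at 1.5× the noise SD and n = 20
  per class, the probability that all five land in the combined-rank top 10
  is ≈ 0.9 — a deliberately demanding setting; single planted features at
  ≥ 3 SD are recovered at rank 1 essentially always.
- **Ties and determinism.** Vote ties break toward the smaller class label;
  rank ties break by first occurrence; category orders are lexicographic;
  axis signs are fixed by the largest loading; run reports exclude
  timestamps so identical configs and seeds rerun byte-identically.
- **Degenerate inputs.** Zero-TIC samples error with the offending sample
  id; constant features get importance 0 and undefined correlations become
  non-edges; zero-variance t-tests return (0, 1) on equal means; empty
  candidate lists annotate to an empty table.

## An end-to-end run

```{r example, eval = FALSE}
des <- synthetic_design(
  samples_per_class = 12, n_bins = 120,
  discriminatory_bins = data.frame(bin = c(136, 152), class = "class2",
                                   shift = 1),
  seed = 17)
sim <- generate_fingerprints(des)
md <- generate_metadata(24, seed = 17)[, c("sample_id", "gender",
                                           "diet_group")]
md$sample_id <- fp_samples(sim$fingerprints)
md$breed <- as.character(sim$labels)

report <- run_breed_analysis(sim$fingerprints, md,
                             run_config(n_bootstraps = 25, n_trees = 200,
                                        seed = 17))
report$classification
autoplot(pc_lda(preprocess_fingerprints(sim$fingerprints), sim$labels))
```

## Known limitations

- Only +1 cation adducts (H, Na, K) and single-¹³C isotopologues are
  enumerated; negative-mode adduct rules and neutral losses are not.
- The Importance Score threshold 0.002 is not portable across forest
  configurations; treat it as a starting point.
- Raw vendor formats and profile-mode spectra are out of scope; inputs are
  centroided peak lists or pre-built matrices in delimited text.
- p-values from the feature t-tests are used for ranking and gating only;
  no multiplicity control is applied across bins.
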