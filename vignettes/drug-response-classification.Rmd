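---
title: "Classifying drug sensitivity from baseline expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying drug sensitivity from baseline expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design decisions taken where more than one reasonable choice existed.

## The problem

Pharmacogenomic cell-line screens summarize each drug–cell-line pair by a
continuous response — an *activity area* (area under the dose–response
curve; higher means more sensitive) or an *IC50* (concentration inhibiting
half of growth; higher means more resistant) — alongside baseline
genome-wide expression. For treatment-relevant questions the binary
distinction (will this line respond?) matters more than the exact value,
so the package reframes response prediction as binary classification with
gene expression as the feature space.

## Response discretization

Per drug, responses are z-scored across all treated cell lines using the
sample standard deviation (n−1). Samples at least 0.8 SD above the mean
are *sensitive* and at least 0.8 SD below are *resistant* when higher
response means more sensitive; the mapping is mirrored for IC50-like
readouts. Boundaries are inclusive, so a sample exactly at ±0.8 is
labelled. The in-between *intermediate* samples are removed from
modelling. Under a Gaussian response, 0.8 SD retains about 2 × 21.2 % of
samples — a deliberate trade of sample size for label purity.

Choices worth noting:

* the z-scoring uses **all** treated cell lines, before any train/test
  split, mirroring the original protocol; fold-local normalization would
  be the leakage-free alternative and can be done by normalizing inside
  each fold by hand;
* a drug whose retained classes fall below `minClassSize` (default 5 per
  class) is *discarded* — a reported outcome, not an error. The default is
  a package choice: skewed response distributions can leave essentially
  one class, where no two-class model is estimable.

## Gene ranking

**F-score** (filter baseline). For gene *i* with class means
$\bar x_i^{(+)}, \bar x_i^{(-)}$ and whole-data mean $\bar x_i$:

$$F(i) = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} - \bar x_i)^2}
{\tfrac{1}{n_+-1}\sum_k (x^{(+)}_{k,i} - \bar x_i^{(+)})^2 +
 \tfrac{1}{n_--1}\sum_k (x^{(-)}_{k,i} - \bar x_i^{(-)})^2}.$$

It is affinely invariant per gene and symmetric in the class labels, but
blind to gene combinations. Degenerate genes: zero numerator and
denominator give F = 0; a positive numerator over a zero denominator gives
F = ∞ (ranked first).

**SVM-RFE** (the workhorse). Iteratively fit a linear soft-margin SVM on
the surviving genes, score each by its squared primal weight, and
eliminate the weakest; eliminated genes fill the ranking from the bottom.
Decisions:

* elimination criterion $w_j^2$ — the standard recursive-elimination
  choice when only "weight" is specified;
* internal cost C = 1; the ranking is fairly insensitive to it and no
  value is prescribed by the protocol;
* features are centred/scaled by training statistics before each fit —
  without this, weights are not comparable across genes;
* the **literal** schedule removes one gene per step (exactly k−1 fits for
  k genes; quadratic cost). The default **chunked** schedule removes 10 %
  of survivors per step while more than 200 survive, then one per step —
  at genome scale the literal rule is impractical, and below 200 genes the
  two schedules coincide;
* all score ties anywhere in the package break lexicographically by gene
  id, so rankings are reproducible.

**Random forest** (embedded baseline): mean decrease in Gini impurity
from a seeded 500-tree forest.

Whether the ranking should be recomputed inside each cross-validation
fold is genuinely open (recomputing is leakage-free; ranking once on all
samples is the cheaper protocol many analyses used). Both are
implemented; per-fold ranking is the default (`rankPerFold`).

## Model tuning

The final classifier is a radial-kernel SVM — the tuned γ grid implies a
radial kernel even though the RFE ranking itself uses a linear one. The
feature count and (C, γ) are chosen by repeated stratified k-fold
cross-validation: defaults of 10 repeats of 10-fold CV over
C ∈ {0.1, 1, 10, 100, 200, 300, 500, 700, 800, 1000} and
γ ∈ {0.1, 0.5, 1, 2, 3, 4, 5, 6, 7, 8}, with a feature grid of
{1…20, 25, 30, 40, 50, 75, 100, 150, 200, 300, 500} clipped to the
universe. Folds are stratified (per-fold class ratio within one member of
proportional) because at realistic class sizes unstratified folds can
lose a class entirely; they are reshuffled every repeat from the seed.
The argmax over mean accuracy breaks ties toward fewer features, then
smaller C, then smaller γ — parsimony first. The per-feature-count
accuracy profile (max over C, γ) typically rises and then falls: too few
genes underfit, too many drown the informative ones, which is also why
feature selection is worth its cost here.

## Cross-cohort harmonization and transfer

Two cohorts measured on different platforms differ per gene in location
and scale. The package adjusts the combined matrix with parametric
empirical-Bayes location/scale batch adjustment (ComBat, via *sva*):
standardize per gene, estimate per-gene-per-batch location/scale, shrink
toward normal / inverse-gamma priors, adjust, and back-transform.
Wrapper contract: a single batch returns the input unchanged; a batch
with fewer than two samples is an error; zero-variance genes pass through
unadjusted with a warning (they cannot be standardized). No biological
covariates enter the design — none are available in this setting.

One subtlety is the **adjustment frame**. Default (pooled) adjustment
pulls *both* batches toward the pooled per-gene distribution. A
classifier frozen on raw cohort A then sees adjusted cohort B still
offset by roughly half the batch shift. A linear decision score is
rank-invariant to such per-gene offsets, but the radial kernel is not —
decision values saturate and transfer quality collapses. The transfer
pipeline therefore anchors the adjustment to the training cohort
(`reference = "a"`, ComBat's reference-batch mode): cohort B is mapped
into cohort A's frame and cohort A is left unchanged, so the frozen
model's feature scaling remains valid. `ebBatchAdjust()` keeps the pooled
default for symmetric use.

Transfer is scored on the validation cohort's own labels (z-scored IC50,
mirrored mapping, intermediates dropped) by:

* accuracy of hard predictions;
* ROC AUC of the continuous decision scores, in the Mann–Whitney
  formulation (ties count one half); positive class = sensitive, scores
  oriented so higher = more sensitive;
* a Welch (unequal-variance) two-sample t-test comparing the normalized
  continuous responses of predicted-sensitive vs predicted-resistant
  samples. The grouping is ambiguous in the source protocol; grouping by
  *predicted* class against measured response is the default, grouping by
  true class against decision score is available (`tGrouping`).

## Ranked-list overlap

To compare two cohorts' gene rankings, the top 1500 genes of each are
tiled into three bins of 500, and each same-tier overlap count k is
tested by Fisher's exact test on

$$\begin{pmatrix} k & 500-k \\ 500-k & N-1000+k \end{pmatrix}$$

over the common universe of N genes. Under independent rankings the
expected overlap per bin is $500^2/N$. The test is two-sided by default
(the usual environment default); one-sided enrichment is available. The
contingency construction is a package choice — same-tier membership
against the rest of the common universe.

## The synthetic-data generator

`generateCohort()` / `generatePairedCohorts()` emulate the data regime the
workflow targets: background expression i.i.d. N(0, 1) per gene and
sample; a small planted set of informative genes whose weighted sum (plus
Gaussian noise) is the latent response; the returned response is the
latent value or its negation depending on the declared orientation; for a
cohort pair, shared informative genes/weights, opposite orientations, and
per-gene distortion $x \mapsto a_g x + b_g$ of the second cohort with
$b_g \sim N(0, \text{batchShift}^2)$ and $a_g$ lognormal centred at 1.
One master seed expands into independent substreams (expression, weights,
batch, noise), so regeneration is bit-identical and changing one field
does not scramble unrelated draws.

Reference conditions (the constructor defaults): 150 cell lines, 1000
genes, 10 informative genes with coefficient magnitude 1.5 (random sign),
unit response noise, batchShift 3, batchScale 1.25. Sample size, response
shape and threshold follow the screens this emulates; the gene count,
effect size and batch scales are package choices of a regime where the
planted signal is recoverable but not trivial.

What the generator does **not** emulate: gene–gene correlation structure,
heavy-tailed microarray intensity distributions, probe-level artifacts,
dose–response curve fitting, and nonlinear genotype–response
relationships. Passing tests on these simulations therefore demonstrate
the correctness and calibration of the machinery, not expected accuracy
on real cohorts — where correlated genes, weaker effects and non-Gaussian
noise make every step harder.

## Numerical choices and degenerate inputs

* Zero-variance response → explicit degenerate-response error; fewer than
  2 samples → error.
* Zero-SD features inside scaling get scale 1 (they contribute a constant
  zero after centring).
* Boundary z-scores are labelled (inclusive thresholds).
* Ties in any ranking or argmax break deterministically (gene id;
  parsimony order in the CV grid).
* All stochastic functions take explicit seeds; pipelines write manifests
  with config snapshots and output checksums, and identical config + seed
  reproduces byte-identical outputs.

## Problem sizes used in the shipped studies

The test-suite and acceptance studies run at deliberately desk-sized
conditions chosen to make their target effects measurable: feature
recovery at n = 120, p = 300 over 20 seeds; the CV profile at n = 150,
p = 300 with two repeats over a reduced grid; batch-effect removal at
2000 genes × 2 × 100 samples with a planted 5-SD shift; null calibration
of the transfer AUC and t-test at n = 500 per cohort and p = 300 (at the
default n = 150 only ~64 labelled samples survive discretization and the
null AUC's sampling spread alone exceeds the ±0.1 calibration band — the
larger cohort makes the band a statement about the method rather than
about sample noise); shared-signal ranked-list overlap at p = 3000 with
50 informative genes and n = 500 (fifty genes sharing the response
variance are individually weak, capped at per-gene correlation
1/√50 ≈ 0.14, so detection needs the larger cohort).

## Known limitations

* The per-gene independence assumption of the F-score and of the
  generator ignores pathway structure.
* Whole-cohort normalization before splitting leaks a small amount of
  test information into training labels (kept for fidelity to the
  emulated protocol; see above).
* The hard decision threshold (score 0) can be mis-calibrated across
  cohorts even when the score ordering is excellent — transfer AUC is the
  more robust transfer metric, and reference-anchored harmonization
  narrows but does not close the gap.
* Only two-batch designs are exercised, though the EB machinery supports
  more.
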