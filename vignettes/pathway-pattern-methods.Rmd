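---
title: "Pathway-pattern prediction of drug combinations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-pattern prediction of drug combinations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combipath)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions they rest on, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The model

The working hypothesis is that an effective drug combination is one whose
two components jointly perturb particular *pairs* of disease pathways. The
pipeline operationalises this in four layers.

**Per-drug differential expression.** Each drug's perturbation is profiled
as treated and control replicate arrays over the same genes, with strictly
positive post-normalisation intensities. `differential_genes()` runs a
per-gene two-sample Student's t-test (pooled variance by default; Welch by
`var_equal = FALSE`) and calls genes with raw p below `alpha` significantly
changed. No multiple-testing correction is applied, deliberately: the gene
calls feed an existential set-intersection in the next layer, not per-gene
inference, and the pathway-level consequences of the per-gene error rate
are controlled there (see *The fingerprinting threshold* below). Genes flat
in both arms get p = 1 rather than NaN, so constant probes can never be
called.

**Pathway-affect fingerprints.** `affected_pathways()` marks pathway *p*
affected when at least one significant gene lies in *p*'s gene set
(upper-cased exact symbol match). The criterion is existential rather than
an enrichment test; it is the weakest reading of "the drug touches this
pathway" and makes the fingerprint a cheap binary vector. The cost of that
choice is a sharp sensitivity to the per-gene false positive rate, which
drives the threshold discussion below.

**Combination features.** Two encodings of an unordered pair (D₁, D₂):

* *Linear addition* (`linear_addition_feature()`): per shared gene,
  (P₁/C₁ − 1) + (P₂/C₂ − 1), with P the mean control and C the mean treated
  intensity. The ratio orientation (control over treated) is kept as the
  method's canonical form; `orientation = "treated_over_control"` flips it
  to the conventional fold-change direction, which only mirrors the feature
  about zero and does not change any downstream classifier's capacity.
  Replicates enter through their arithmetic means.
* *Frequent pattern* (`extract_patterns()`, `frequency_scores()`): the pair
  realises pattern {i, j} when one drug affects pathway i and the other
  affects j (i = j allowed; diagonal patterns are excludable by
  `include_diagonal = FALSE`). Pattern {i, j} is scored
  S = N(EC) / (N(RC) + s): its count among the known effective pairs over
  its expected count among random re-pairings of the same drugs. The
  background count is estimated from `n_random` draws (default 10× the
  effective-set size) and rescaled to the effective-set size so numerator
  and denominator are commensurable; the pseudocount s (default 1) keeps
  scores finite and shrinks patterns with near-zero background. High S
  means "seen among effective combinations far more than chance
  re-pairing predicts".

**Classification.** `build_dataset()` turns labelled pairs into a feature
matrix (continuous per-gene values, or binary indicators of the selected
patterns). Negative pairs are random re-pairings of the positive set's
drugs, disjoint from the positives, by default equal in number — a balanced
design matching how the positive set is typically curated. Classifiers:
two-class SVMs with four kernels, a one-class SVM on positives only, and a
naive Bayes written in-package (below).

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `alpha` (per-gene) | 0.05 | conventional per-test level for a signature used on its own |
| `alpha` (pipeline fingerprinting) | 0.001 | see threshold discussion below |
| `min_replicates` | 3 | minimum arms for a t-test with any stability |
| `n_random` | 10 × #effective | background draws; 10× halves the scaled-count noise versus 1× at negligible cost |
| `pseudocount` | 1 | standard add-one shrinkage of the background |
| feature count | ⌊n/4⌋ | keeps model capacity proportionate to a small sample |
| SVM grid | 2⁻⁵…2⁵, ×2 steps | log grid over both `c` and `g`; kernel-scale parameters act multiplicatively, so log spacing is the meaningful resolution |
| `nu` (one-class) | 0.1 | bounds the training-outlier fraction at 10% |
| `smoothing` | 1 | Laplace pseudocount for Bernoulli features |

## The fingerprinting threshold

The existential affect criterion composes badly with a liberal per-gene
threshold. If a pathway holds m genes and the per-gene false-positive rate
is α, a completely unperturbed pathway is still called affected with
probability 1 − (1 − α)^m. At α = 0.05 and m = 25 that is ≈ 0.72: nearly
every fingerprint bit saturates to 1 on null data alone, and pattern scores
carry no information. Conversely a genuinely affected pathway has *all* its
member genes shifted, so its detection probability is
1 − (1 − power)^m ≈ 1 even when per-gene power is modest. The pipeline
therefore fingerprint-calls genes at α = 0.001 (per-pathway false-affect
≈ 2.5% at m = 25) while `differential_genes()` keeps 0.05 as its
stand-alone default. Both are configurable; the right value scales
inversely with pathway size.

## Naive Bayes by mergeable sufficient statistics

The classifier itself is textbook: class priors by frequency;
class-conditional Bernoulli with Laplace smoothing (count + s)/(n + 2s) for
binary features; class-conditional Gaussians (variance floored at 1e-9) for
continuous ones; prediction in log space with posteriors normalised per row
and ties to the first class.

What the package makes explicit is the *training decomposition*: everything
the model needs is the per-class count and the per-feature per-class sum
and sum of squares. `nb_map()` computes these on any slice of the data;
`nb_reduce()` adds them component-wise and builds the model. Because the
statistics are purely additive, the partitioned fit equals the sequential
`nb_fit()` *exactly* in every count and to summation-order rounding
(≤ 1e-12) in every probability, for any disjoint partitioning — including
empty slices, which are additive identities. This identity is the testable
core of running the training as independent jobs over data shards, and the
test suite asserts it for 1, 2 and 5 random partitions. Feature types in
`nb_reduce()` are inferred from the statistics themselves (a 0/1 feature
satisfies Σx = Σx² with Σx ≤ n) or can be passed explicitly.

## Evaluation protocols

Confusion counts are pooled across folds before computing ACC, SN, SP and
F₁ (micro-averaging): LOOCV forces pooling, and using one convention
everywhere keeps protocols comparable; a per-fold breakdown is also
returned. Undefined ratios (empty denominator) are reported as `NA`, never
coerced to 0. Folds are stratified by class and dealt round-robin over one
globally shuffled sequence, which makes k = n reduce exactly to
leave-one-out; unstratified assignment is available by flag. The repeated
independent split holds out 20% (stratified) and reports one row per run
plus an arithmetic-mean row — the mean of per-run ratios, matching the
run-table layout, rather than a ratio of pooled counts. For the one-class
protocol, LOOCV trains on the remaining positives and scores the held-out
positive; specificity is undefined there and reported as `NA`.

## The synthetic generator

`make_study()` emulates the data shape the pipeline consumes, with planted,
fully recoverable structure: lognormal baseline expression (meanlog
log 100, per-gene spread 0.5 — positive support and microarray-like skew),
multiplicative treatment shifts of exp(`effect_size`) applied to every gene
of a drug's truly affected pathways, i.i.d. replicate noise of `noise_sd`
on the log scale, disjoint pathway gene sets when they fit the gene pool,
and an effective-pair list constructed so each pair co-realises one of the
planted pathway-pair patterns.

Default conditions: 40 drugs, 500 genes, 20 pathways × 25 genes, 3 + 3
replicates, 20 effective pairs, effect size 1.0 with noise 0.2 (a 5-sigma
per-replicate shift), background affect rate 0.05, five disjoint planted
patterns. The last two are chosen so each planted pattern recurs in ~4
effective pairs (countable enrichment) while a random re-pairing
accidentally co-realises some planted pattern only rarely — with many pairs
sharing one pattern, or a dense background, "effective" would stop being
equivalent to "co-realises a planted pattern" and the negatives would carry
substantial label noise by construction.

What passing on this generator shows: the pipeline's stages compose
correctly and recover planted structure under honest noise at desk scale.
What it does not show: performance on real compendia — the generator has no
batch effects, no cell-line or dosing structure, no gene-gene correlation
within arrays, no overlap between pathway gene sets, and pathway effects
shift all member genes uniformly, all of which make real fingerprints
noisier than synthetic ones.

## Numerical choices and degenerate inputs

* t statistics on zero-variance genes: p = 1, statistic 0 (never
  significant).
* Mutual information for mRMR uses 3-bin discretisation at mean ± 1 sd
  (binary features pass through); plug-in estimate in nats; ties in the
  greedy objective break to the lowest column index, and top-k pattern
  selection breaks score ties by higher effective-count then pattern id —
  both orderings fully deterministic.
* Grid-search ties break to smaller `c`, then smaller `g`.
* The one-class boundary `nu = 1` is mapped to the nearest interior value
  (1 − 1e-6) because the underlying solver degenerates exactly at 1.
* SVM features are not rescaled by the wrapper: pattern features are
  already 0/1, linear-addition features are centred ratios; rescaling is
  the caller's decision, not a hidden step.
* All stochastic steps (generation, background draws, fold shuffles,
  splits, negative sampling) take explicit integer seeds, and the pipeline
  derives stage seeds from one master seed.

## Problem sizes used in validation

The test suite and the reproduction script run at the generator's default
scale (40 drugs / 500 genes / 20 pathways; 40-pair datasets), with 10–50
seed replicates for the stochastic properties and coarser powers-of-four
grids where several grid searches are compared — sizes chosen as the
package's desk-scale validation conditions, orders of magnitude below a
real expression compendium by design.

## Known limitations

* The existential affect criterion ignores effect direction and magnitude;
  a pathway touched by one strongly shifted gene equals one with all genes
  shifted.
* Pattern features are binary: the model cannot weight a pattern more
  strongly for being realised through many pathway-gene routes.
* The negative class is random re-pairing, so some "negatives" may be
  undiscovered effective pairs; the one-class protocol exists precisely to
  drop that assumption.
* Linear-addition features assume the combination effect is additive in
  centred expression ratios; synergistic or antagonistic interactions are
  invisible to it.
* Only pairwise combinations are modelled.
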