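# combipath

Predicting effective pairwise drug combinations from the pathways their
component drugs perturb.

## The problem

Exhaustively screening drug pairs in the lab is infeasible — the candidate
space grows quadratically in the number of single agents. `combipath`
implements a transcriptome-driven screen: if two drugs, each profiled
individually on a treated-vs-control microarray design, jointly perturb the
disease-pathway combinations that known effective drug pairs perturb, the
pair is a candidate combination therapy.

The pipeline:

1. **Per-drug signatures.** For each drug, a two-sample Student's t-test
   (pooled variance; Welch optional) per gene between treated and control
   replicate arrays gives the significantly changed gene set.
2. **Pathway-affect fingerprints.** A pathway *p* (a GMT gene set, e.g. the
   MSigDB disease-pathway collection) is *affected* by a drug when at least
   one significantly changed gene lies in *p*. Each drug becomes a binary
   vector over pathways.
3. **Combination features.** Two encodings of a pair (D₁, D₂):
   * *linear addition* — per shared gene G, with P the mean control and C
     the mean treated expression,

     ```
     D₁,₂|G = (P₁|G / C₁|G − 1) + (P₂|G / C₂|G − 1)
     ```
   * *frequent pattern* — a *pattern* {i, j} is a pathway pair with i
     affected by one drug and j by the other. Each pattern is scored by its
     frequency among known effective combinations relative to random
     re-pairings of the same drugs,

     ```
     S_ij = N_ij(EC) / (N_ij(RC) + s)
     ```

     with N(RC) scaled to the effective-set size and pseudocount s (default
     1). Pairs are then encoded as binary indicators of the top-scoring
     patterns.
4. **Feature selection.** Greedy mRMR (MID variant, 3-bin discretisation)
   for the continuous encoding; frequency-score thresholding for patterns;
   feature count defaults to ⌊n/4⌋ samples.
5. **Classifiers.** Two-class SVM (linear / polynomial / Gaussian / tanh
   kernels, libsvm via e1071) with seeded grid search for cost `c` and
   kernel coefficient `g` over [2⁻⁵, 2⁵]; a one-class SVM novelty detector
   trained on effective pairs only; and a from-scratch naive Bayes whose
   training runs over mergeable per-partition sufficient statistics
   (`nb_map()` / `nb_reduce()`) and is exactly equal to the sequential fit —
   the testable core of scaling the classifier out over data slices.
6. **Evaluation.** Pooled-count k-fold CV, LOOCV (including the one-class
   protocol), and repeated stratified 4:1 independent splits, reporting
   ACC, SN, SP and F₁ = 2TP/(FP + FN + 2TP).

A fully seeded synthetic generator (`make_study()`) plants known
pathway-pair enrichments so every stage can be validated against ground
truth without any external download.

## Worked example

```r
library(combipath)

sim    <- make_study(synthetic_config(seed = 42))        # 40 drugs, 20 pathways
vecs   <- pathway_fingerprints(sim$studies, sim$pathways, alpha = 0.001)
scores <- frequency_scores(sim$effective_pairs, vecs, seed = 43)
head(scores, 5)
#>   pattern pathway_i pathway_j  n_ec  n_rc score
#> 1 9:10    PW09      PW10          4   0.8  2.22
#> 2 18:19   PW18      PW19          2   0.2  1.67
#> 3 3:4     PW03      PW04          4   1.8  1.43
#> 4 5:6     PW05      PW06          4   1.8  1.43
#> 5 7:8     PW07      PW08          4   1.9  1.38
```

Four of the five top-scoring patterns are the generator's planted pathway
pairs (`9:10`, `3:4`, `5:6`, `7:8`): each occurs in 4 of the 20 effective
pairs but only ~1–2 times per 20 random re-pairings (the scaled `n_rc`). Building the balanced dataset and
tuning a Gaussian-kernel SVM:

```r
neg   <- generate_negative_pairs(sim$effective_pairs, seed = 44)
pairs <- dplyr::bind_rows(
  dplyr::mutate(sim$effective_pairs, label = "effective"),
  dplyr::mutate(neg, label = "noneffective"))
sel <- select_frequent_patterns(scores, default_feature_count(nrow(pairs)))
ds  <- build_dataset(pairs, "frequent_pattern", vectors = vecs, patterns = sel)

gs <- grid_search(ds, "gaussian", folds = 10, seed = 45)
gs
#> <grid_search> gaussian kernel over 121 points: best c = 8, g = 0.5 (CV accuracy 0.875)

kfold_cv(svm_trainer(gs$best), ds, k = 10, seed = 46)
#> <cv_result> 10-fold CV: ACC 0.875, SN 0.950, SP 0.800, F1 0.884
```

So on this planted collection the pattern features recover 87.5% ten-fold
CV accuracy: 19 of 20 effective pairs and 16 of 20 random pairings
classified correctly, with the one planted-pattern-free margin of error the
generator's background affect rate predicts.

The whole run is also available as one call / one shell command:

```r
run_pipeline(pipeline_config(out_dir = "run1", synthetic = TRUE, seed = 1))
```

```sh
Rscript inst/cli/combipath.R run --config config.yaml
```

See `vignettes/pathway-pattern-methods.Rmd` for the model assumptions,
parameter choices and limitations.

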