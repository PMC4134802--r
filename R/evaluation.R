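#' Confusion counts from labels and predictions
#'
#' @param truth,prediction Vectors of class labels.
#' @param positive The positive-class label (default `"effective"`).
#' @return A named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, prediction, positive = "effective") {
  truth <- as.character(truth)
  prediction <- as.character(prediction)
  if (length(truth) != length(prediction)) {
    abort("truth and prediction differ in length.", class = "combipath_error")
  }
  list(
    tp = sum(truth == positive & prediction == positive),
    fp = sum(truth != positive & prediction == positive),
    tn = sum(truth != positive & prediction != positive),
    fn = sum(truth == positive & prediction != positive)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and F-measure `2TP/(FP+FN+2TP)`. A zero denominator yields
#' `NA` — an undefined ratio is reported as missing, never coerced to 0.
#'
#' @param counts A list with `tp`, `fp`, `tn`, `fn` (see [confusion_counts()]).
#' @return A one-row tibble: `acc`, `sn`, `sp`, `f1` plus the four counts.
#' @examples
#' compute_metrics(list(tp = 3, fp = 1, tn = 2, fn = 2))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) {
    abort("Counts must be non-negative.", class = "combipath_error")
  }
  total <- tp + fp + tn + fn
  if (total == 0) {
    abort("No evaluated samples.", class = "combipath_error")
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    acc = (tp + tn) / total,
    sn = ratio(tp, tp + fn),
    sp = ratio(tn, tn + fp),
    f1 = ratio(2 * tp, fp + fn + 2 * tp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# Stratified, seeded fold assignment: indices are shuffled within class,
# concatenated class by class, and dealt round-robin over the k folds in one
# global sequence. The continuation across classes keeps folds balanced and
# makes k = n reduce to exactly one sample per fold (the LOOCV layout).
make_folds <- function(y, k, seed) {
  order_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(y), as.character(y)),
                  function(idx) idx[sample.int(length(idx))]),
           use.names = FALSE)
  })
  fold <- integer(length(y))
  fold[order_idx] <- rep(seq_len(k), length.out = length(y))
  fold
}

#' k-fold cross-validation
#'
#' Stratified shuffled folds (seeded); each fold is held out once, the
#' trainer is fitted on the rest, and confusion counts are pooled over all
#' folds before computing metrics (micro-averaging — the convention forced by
#' LOOCV, applied uniformly). A per-fold (macro) breakdown is also returned.
#'
#' @param trainer A trainer function, see [svm_trainer()].
#' @param dataset A [combination_dataset()].
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Seed for the fold shuffle.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return A `cv_result` list: `pooled` (one-row metrics tibble), `per_fold`
#'   tibble, `folds` (the assignment vector), `k`, `seed`.
#' @export
kfold_cv <- function(trainer, dataset, k = 10, seed = 1L, stratified = TRUE) {
  n <- nrow(dataset$X)
  if (k < 2 || k > n) {
    abort(sprintf("k must be in [2, %d].", n), class = "combipath_error")
  }
  fold <- if (stratified) make_folds(dataset$y, k, seed)
          else withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  truth <- character(0)
  pred <- character(0)
  per_fold <- vector("list", k)
  skipped <- 0L
  needs_both <- isTRUE(attr(trainer, "needs_both_classes"))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0L) next
    train_ds <- subset_dataset(dataset, -test_idx)
    if (needs_both && nlevels(droplevels(train_ds$y)) < 2L) {
      warn(sprintf("Fold %d skipped: training split is single-class.", f))
      skipped <- skipped + 1L
      next
    }
    predict_fn <- trainer(train_ds)
    p <- as.character(predict_fn(dataset$X[test_idx, , drop = FALSE]))
    truth <- c(truth, as.character(dataset$y[test_idx]))
    pred <- c(pred, p)
    per_fold[[f]] <- dplyr::mutate(
      compute_metrics(confusion_counts(dataset$y[test_idx], p)),
      fold = f, .before = 1)
  }
  pooled <- compute_metrics(confusion_counts(truth, pred))
  structure(
    list(pooled = pooled,
         per_fold = dplyr::bind_rows(per_fold),
         folds = fold, k = k, seed = seed, n_skipped = skipped),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV: ACC %.3f, SN %.3f, SP %.3f, F1 %.3f\n",
              x$k, x$pooled$acc, x$pooled$sn, x$pooled$sp, x$pooled$f1))
  invisible(x)
}

#' @rdname kfold_cv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-fold metric tibble; `glance()`: the pooled row.
#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @rdname kfold_cv
#' @export
glance.cv_result <- function(x, ...) x$pooled

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a model trained on the remaining n - 1;
#' confusion counts are pooled. Works for one-class trainers too: held-out
#' positives are scored by a model trained on the other positives. For
#' two-class trainers a training split that degenerates to a single class is
#' skipped with a warning and reported in `n_skipped`.
#'
#' @inheritParams kfold_cv
#' @return A `cv_result` (with `k = n`).
#' @export
loocv <- function(trainer, dataset) {
  n <- nrow(dataset$X)
  if (n < 2L) {
    abort("Need >= 2 samples for LOOCV.", class = "combipath_error")
  }
  truth <- character(0)
  pred <- character(0)
  skipped <- 0L
  needs_both <- isTRUE(attr(trainer, "needs_both_classes"))
  for (i in seq_len(n)) {
    train_ds <- subset_dataset(dataset, -i)
    if (needs_both && nlevels(droplevels(train_ds$y)) < 2L) {
      warn(sprintf("Sample %d skipped: training split is single-class.", i))
      skipped <- skipped + 1L
      next
    }
    predict_fn <- trainer(train_ds)
    truth <- c(truth, as.character(dataset$y[i]))
    pred <- c(pred, as.character(predict_fn(dataset$X[i, , drop = FALSE])))
  }
  pooled <- compute_metrics(confusion_counts(truth, pred))
  structure(
    list(pooled = pooled, per_fold = tibble(), folds = seq_len(n),
         k = n, seed = NA_integer_, n_skipped = skipped),
    class = "cv_result"
  )
}

#' Repeated stratified train/test split evaluation
#'
#' Mimics an independent test: the dataset is split into training and test
#' sets at `train_fraction` (default 4:1), the trainer is fitted on the
#' training part and scored on the held-out part, and the whole procedure is
#' repeated. The result is one metrics row per run plus an arithmetic-mean
#' row labelled `"average"`.
#'
#' @inheritParams kfold_cv
#' @param train_fraction Fraction of samples used for training, in (0, 1);
#'   default 0.8.
#' @param repeats Number of random splits (default 10).
#' @return A `split_eval` tibble: `run` (1..repeats, then `"average"`),
#'   `acc`, `sn`, `sp`, `f1` and the confusion counts (NA on the mean row for
#'   the counts).
#' @export
repeated_split_eval <- function(trainer, dataset, train_fraction = 0.8,
                                repeats = 10, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be in (0, 1).", class = "combipath_error")
  }
  n <- nrow(dataset$X)
  runs <- purrr::map_dfr(seq_len(repeats), function(r) {
    train_idx <- withr::with_seed(seed + r - 1L, {
      unlist(lapply(split(seq_len(n), dataset$y), function(idx) {
        idx[sample.int(length(idx), round(train_fraction * length(idx)))]
      }), use.names = FALSE)
    })
    test_idx <- setdiff(seq_len(n), train_idx)
    train_ds <- subset_dataset(dataset, train_idx)
    if (nlevels(droplevels(train_ds$y)) < 2L) {
      abort("Training split lost a class; lower train_fraction or add samples.",
            class = "combipath_error")
    }
    predict_fn <- trainer(train_ds)
    p <- predict_fn(dataset$X[test_idx, , drop = FALSE])
    dplyr::mutate(compute_metrics(confusion_counts(dataset$y[test_idx], p)),
                  run = as.character(r), .before = 1)
  })
  avg <- dplyr::summarise(runs, dplyr::across(c("acc", "sn", "sp", "f1"),
                                              ~ mean(.x, na.rm = TRUE)))
  avg <- dplyr::mutate(avg, run = "average",
                       tp = NA_integer_, fp = NA_integer_,
                       tn = NA_integer_, fn = NA_integer_, .before = 1)
  avg <- avg[, names(runs)]
  out <- dplyr::bind_rows(runs, avg)
  class(out) <- c("split_eval", class(out))
  out
}

#' Write an evaluation table as TSV
#'
#' Mirrors the run-per-row layout of an independent-test report: `run`,
#' `acc`, `sn`, `sp`, `f1` (and counts), with a final average row.
#'
#' @param result A `split_eval` tibble (or any metrics tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(result, path) {
  readr::write_tsv(as_tibble(as.data.frame(result)), path)
  invisible(path)
}
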