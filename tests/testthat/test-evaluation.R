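test_that("metrics follow the confusion-count formulas", {
  m <- compute_metrics(list(tp = 3, fp = 1, tn = 2, fn = 2))
  expect_equal(m$acc, 0.625)
  expect_equal(m$sn, 0.6)
  expect_equal(m$sp, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 3 / (1 + 2 + 6), tolerance = 1e-12)

  perfect <- compute_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(perfect[c("acc", "sn", "sp", "f1")]),
               c(acc = 1, sn = 1, sp = 1, f1 = 1))

  degenerate <- compute_metrics(list(tp = 0, fp = 0, tn = 3, fn = 2))
  expect_equal(degenerate$sn, 0)
  expect_equal(degenerate$f1, 0)
  # undefined ratios are NA, never coerced to zero
  no_neg <- compute_metrics(list(tp = 4, fp = 0, tn = 0, fn = 1))
  expect_true(is.na(no_neg$sp))
  expect_error(compute_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               class = "combipath_error")
})

test_that("metrics match a brute-force recount on random prediction lists", {
  withr::with_seed(22, {
    for (case in 1:200) {
      n <- sample(1:30, 1)
      truth <- sample(c("effective", "noneffective"), n, replace = TRUE)
      pred <- sample(c("effective", "noneffective"), n, replace = TRUE)
      got <- compute_metrics(confusion_counts(truth, pred))
      want <- oracle_metrics(truth, pred)
      expect_equal(got$acc, want$acc)
      expect_equal(got$sn, want$sn)
      expect_equal(got$sp, want$sp)
      expect_equal(got$f1, want$f1)
    }
  })
})

test_that("k-fold with k = n reproduces leave-one-out exactly", {
  ds <- fixture_dataset(n = 14, p = 2, seed = 24, binary = FALSE, separation = 1)
  tr <- nb_trainer()
  kn <- kfold_cv(tr, ds, k = 14, seed = 5)
  loo <- loocv(tr, ds)
  expect_equal(kn$pooled[c("acc", "sn", "sp", "f1", "tp", "fp", "tn", "fn")],
               loo$pooled[c("acc", "sn", "sp", "f1", "tp", "fp", "tn", "fn")])
})

test_that("majority-vote predictions pool to the label frequency exactly", {
  ds <- fixture_dataset(n = 20, p = 2, seed = 26, binary = TRUE)
  # rebuild with a 12/8 split
  y <- rep(c("effective", "noneffective"), c(12, 8))
  ds <- combination_dataset(ds$pairs, ds$X, y, ds$feature_ids)
  for (k in c(4, 5, 10, 20)) {
    cv <- kfold_cv(majority_trainer(), ds, k = k, seed = k)
    expect_equal(cv$pooled$acc, 0.6, info = paste("k =", k))
  }
})

test_that("fold assignment is seeded, stratified and order-invariant", {
  ds <- fixture_dataset(n = 20, p = 2, seed = 28, binary = FALSE, separation = 2)
  a <- kfold_cv(nb_trainer(), ds, k = 5, seed = 9)
  b <- kfold_cv(nb_trainer(), ds, k = 5, seed = 9)
  expect_identical(a$folds, b$folds)
  expect_equal(a$pooled, b$pooled)
  # each fold holds 2 of each class for a balanced 10+10 design
  tab <- table(a$folds, ds$y)
  expect_true(all(tab == 2))
})

test_that("LOOCV covers dummy geometries and the one-class protocol", {
  # two tight clusters, nearest neighbour is certain
  X <- rbind(matrix(c(0, 0.1, 0, 0.1), 2, 2), matrix(c(5, 5.1, 5, 5.1), 2, 2))
  ds <- combination_dataset(
    tibble::tibble(drug_a = c("a", "b", "c", "d"), drug_b = c("e", "f", "g", "h")),
    X, c("effective", "effective", "noneffective", "noneffective"),
    c("f1", "f2"))
  expect_equal(loocv(nn_trainer(), ds)$pooled$acc, 1)

  # constant predictor: SN 1 / SP 0
  const_trainer <- function() {
    f <- function(train) function(Xn)
      factor(rep("effective", nrow(Xn)), levels = c("effective", "noneffective"))
    attr(f, "needs_both_classes") <- FALSE
    f
  }
  cc <- loocv(const_trainer(), ds)$pooled
  expect_equal(cc$sn, 1)
  expect_equal(cc$sp, 0)

  # one-class variant: held-out positives scored by a model on the rest
  withr::with_seed(30, Xp <- matrix(rnorm(40, sd = 0.4), 20, 2))
  pos <- combination_dataset(
    tibble::tibble(drug_a = sprintf("a%d", 1:20), drug_b = sprintf("b%d", 1:20)),
    Xp, rep("effective", 20), c("f1", "f2"))
  res <- loocv(one_class_trainer(kind = "gaussian", g = 1, nu = 0.1), pos)
  expect_true(is.na(res$pooled$sp))   # no negatives in the protocol
  expect_gte(res$pooled$acc, 0.5)     # most held-out positives look effective
})

test_that("repeated splits report one row per run plus a correct mean row", {
  ds <- fixture_dataset(n = 30, p = 2, seed = 32, binary = FALSE, separation = 4)
  tbl <- repeated_split_eval(nb_trainer(), ds, repeats = 5, seed = 3)
  expect_equal(nrow(tbl), 6)
  expect_equal(tbl$run, c(as.character(1:5), "average"))
  runs <- tbl[tbl$run != "average", ]
  expect_equal(tbl$acc[6], mean(runs$acc))
  expect_equal(tbl$f1[6], mean(runs$f1))
  # single repeat: average equals the run
  one <- repeated_split_eval(nb_trainer(), ds, repeats = 1, seed = 3)
  expect_equal(one$acc[1], one$acc[2])
  # perfectly separated data: average accuracy 1
  expect_equal(tbl$acc[6], 1)
  expect_identical(repeated_split_eval(nb_trainer(), ds, repeats = 3, seed = 8),
                   repeated_split_eval(nb_trainer(), ds, repeats = 3, seed = 8))
  expect_error(repeated_split_eval(nb_trainer(), ds, train_fraction = 1.2),
               class = "combipath_error")
})
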