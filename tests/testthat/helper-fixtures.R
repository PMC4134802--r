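# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops over textbook formulas, separate from the package's
# vectorised implementations.

# study with explicit replicate values (one row per gene)
fixture_study <- function(drug_id = "d1", treated, control,
                          genes = paste0("G", seq_len(nrow(as.matrix(treated))))) {
  expression_study(drug_id, genes, as.matrix(treated), as.matrix(control))
}

# constant-replicate study: every treated column = tr, control column = ct
constant_study <- function(drug_id, tr, ct, reps = 2) {
  fixture_study(drug_id,
                matrix(rep(tr, reps), ncol = reps),
                matrix(rep(ct, reps), ncol = reps))
}

# pooled-variance two-sample t statistic, textbook formula
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# brute-force confusion recount from raw label/prediction lists
oracle_metrics <- function(truth, pred) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "effective") {
      if (pred[i] == "effective") tp <- tp + 1 else fn <- fn + 1
    } else {
      if (pred[i] == "effective") fp <- fp + 1 else tn <- tn + 1
    }
  }
  total <- tp + fp + tn + fn
  list(acc = (tp + tn) / total,
       sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       f1 = if (fp + fn + 2 * tp == 0) NA_real_ else 2 * tp / (fp + fn + 2 * tp))
}

# plug-in mutual information from a contingency table, nested loops
oracle_mi <- function(x, y) {
  xs <- unique(x); ys <- unique(y)
  n <- length(x); total <- 0
  for (a in xs) for (b in ys) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      total <- total + pxy * log(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
    }
  }
  total
}

oracle_discretize <- function(v) {
  if (all(v %in% c(0, 1))) return(v)
  m <- mean(v); s <- sd(v)
  if (s == 0) return(rep(0, length(v)))
  out <- integer(length(v))
  for (i in seq_along(v)) {
    out[i] <- if (v[i] < m - s) 0L else if (v[i] < m + s) 1L else 2L
  }
  out
}

# exhaustive greedy mRMR (MID) trace, independent of the implementation
oracle_mrmr <- function(X, y, k) {
  p <- ncol(X)
  D <- lapply(seq_len(p), function(j) oracle_discretize(X[, j]))
  rel <- vapply(D, oracle_mi, numeric(1), y = y)
  sel <- integer(0)
  while (length(sel) < k) {
    rem <- setdiff(seq_len(p), sel)
    best <- NA; best_obj <- -Inf
    for (f in rem) {
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(s) oracle_mi(D[[f]], D[[s]]), numeric(1)))
      obj <- rel[f] - red
      if (obj > best_obj + 1e-12) { best <- f; best_obj <- obj }
    }
    sel <- c(sel, best)
  }
  sel
}

# random labelled dataset for model-level tests
fixture_dataset <- function(n = 20, p = 4, seed = 1, binary = TRUE,
                            separation = 0) {
  withr::with_seed(seed, {
    y <- rep(c("effective", "noneffective"), length.out = n)
    X <- if (binary) {
      base <- matrix(rbinom(n * p, 1, 0.5), n, p)
      if (separation > 0) base[, 1] <- as.integer(y == "effective")
      base
    } else {
      off <- ifelse(y == "effective", separation, -separation)
      matrix(rnorm(n * p, sd = 1), n, p) + off
    }
    drugs <- sprintf("D%02d", seq_len(2 * n))
    pairs <- tibble::tibble(drug_a = drugs[seq_len(n)],
                            drug_b = drugs[n + seq_len(n)])
    combination_dataset(pairs, X, y, paste0("f", seq_len(p)))
  })
}

# trainer that always predicts the training fold's majority class
majority_trainer <- function() {
  f <- function(train) {
    tab <- table(train$y)
    lab <- names(tab)[which.max(tab)]
    function(X) factor(rep(lab, nrow(X)), levels = c("effective", "noneffective"))
  }
  attr(f, "needs_both_classes") <- FALSE
  f
}

# 1-nearest-neighbour trainer for geometric sanity checks
nn_trainer <- function() {
  f <- function(train) {
    Xtr <- train$X; ytr <- as.character(train$y)
    function(X) {
      X <- as.matrix(X)
      lab <- vapply(seq_len(nrow(X)), function(i) {
        d <- rowSums((Xtr - matrix(X[i, ], nrow(Xtr), ncol(Xtr), byrow = TRUE))^2)
        ytr[which.min(d)]
      }, character(1))
      factor(lab, levels = c("effective", "noneffective"))
    }
  }
  attr(f, "needs_both_classes") <- FALSE
  f
}
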