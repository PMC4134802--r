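# Naive Bayes written from scratch around mergeable sufficient statistics:
# the partition-aggregate (map/reduce) fit and the single-pass fit share the
# model-building step, so the two routes agree exactly in counts and to
# floating-point summation order in the probabilities.

NB_VAR_FLOOR <- 1e-9

nb_feature_types <- function(X) {
  ifelse(apply(X, 2, function(col) all(col %in% c(0, 1))), "binary", "continuous")
}

#' Per-partition sufficient statistics for naive Bayes
#'
#' Computes the class counts and, per feature and class, the sum and sum of
#' squares needed to fit the model. Statistics are mergeable: the statistics
#' of a union of disjoint partitions are the component-wise sums of the
#' partition statistics, which is what makes the classifier trainable by
#' independent workers over data slices.
#'
#' @param partition A [combination_dataset()] slice (possibly empty).
#' @param classes Class levels; defaults to the dataset's label levels.
#' @return A `partition_stats` list: `classes`, `feature_ids`, `n` (class
#'   counts), `sum` and `sumsq` (feature x class matrices).
#' @export
nb_map <- function(partition, classes = levels(partition$y)) {
  X <- partition$X
  y <- factor(partition$y, levels = classes)
  p <- ncol(X)
  n <- setNames(as.numeric(table(y)), classes)
  sum_m <- matrix(0, nrow = p, ncol = length(classes),
                  dimnames = list(colnames(X), classes))
  sumsq_m <- sum_m
  for (cl in classes) {
    rows <- which(y == cl)
    if (length(rows) > 0L) {
      Xc <- X[rows, , drop = FALSE]
      sum_m[, cl] <- colSums(Xc)
      sumsq_m[, cl] <- colSums(Xc^2)
    }
  }
  structure(list(classes = classes, feature_ids = colnames(X),
                 n = n, sum = sum_m, sumsq = sumsq_m),
            class = "partition_stats")
}

merge_stats <- function(stats_list) {
  stats_list <- purrr::discard(stats_list, function(s) sum(s$n) == 0)
  if (length(stats_list) == 0L) {
    abort("All partitions are empty.", class = "combipath_error")
  }
  base <- stats_list[[1]]
  for (s in stats_list[-1]) {
    if (!identical(s$classes, base$classes) ||
        !identical(s$feature_ids, base$feature_ids)) {
      abort("Partition statistics disagree on classes or features.",
            class = "combipath_error")
    }
    base$n <- base$n + s$n
    base$sum <- base$sum + s$sum
    base$sumsq <- base$sumsq + s$sumsq
  }
  base
}

# Turn aggregated sufficient statistics into model parameters. Binary
# features get Laplace-smoothed Bernoulli rates; continuous features get
# per-class mean and variance (variance floored so likelihoods stay proper).
nb_model_from_stats <- function(stats, feature_types, smoothing) {
  classes <- stats$classes
  n <- stats$n
  if (any(n == 0)) {
    abort("Both classes must be present to fit naive Bayes.",
          class = "combipath_error")
  }
  priors <- n / sum(n)
  p <- length(stats$feature_ids)
  bern <- matrix(NA_real_, p, length(classes),
                 dimnames = list(stats$feature_ids, classes))
  mu <- bern
  sigma2 <- bern
  for (cl in classes) {
    nc <- n[[cl]]
    s <- stats$sum[, cl]
    ss <- stats$sumsq[, cl]
    is_bin <- feature_types == "binary"
    bern[is_bin, cl] <- (s[is_bin] + smoothing) / (nc + 2 * smoothing)
    mu[!is_bin, cl] <- s[!is_bin] / nc
    v <- (ss[!is_bin] - s[!is_bin]^2 / nc) / max(nc - 1, 1)
    sigma2[!is_bin, cl] <- pmax(v, NB_VAR_FLOOR)
  }
  structure(
    list(classes = classes, priors = priors,
         feature_ids = stats$feature_ids, feature_types = feature_types,
         bernoulli = bern, mean = mu, var = sigma2,
         smoothing = smoothing, class_counts = stats$n),
    class = "nb_model"
  )
}

#' Fit a naive Bayes classifier
#'
#' Event model per feature type: binary 0/1 features are modelled as
#' class-conditional Bernoulli with Laplace smoothing
#' `(count + s) / (n_class + 2s)`; continuous features as class-conditional
#' Gaussians (variance floored at 1e-9). Priors are class frequencies.
#'
#' @param dataset A [combination_dataset()] with both classes present.
#' @param smoothing Laplace pseudocount `s` (default 1).
#' @return An `nb_model`.
#' @export
nb_fit <- function(dataset, smoothing = 1) {
  X <- dataset$X
  y <- dataset$y
  classes <- levels(y)
  types <- nb_feature_types(X)
  n <- setNames(as.numeric(table(y)), classes)
  sum_m <- matrix(0, ncol(X), length(classes),
                  dimnames = list(colnames(X), classes))
  sumsq_m <- sum_m
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    sum_m[, cl] <- colSums(Xc)
    sumsq_m[, cl] <- colSums(Xc^2)
  }
  stats <- structure(list(classes = classes, feature_ids = colnames(X),
                          n = n, sum = sum_m, sumsq = sumsq_m),
                     class = "partition_stats")
  nb_model_from_stats(stats, types, smoothing)
}

#' Aggregate partition statistics into a naive Bayes model
#'
#' Sums the sufficient statistics of disjoint partitions (empty partitions
#' are ignored) and builds the same model [nb_fit()] would produce on the
#' concatenated data: counts agree exactly, probabilities to summation-order
#' rounding.
#'
#' @param stats_list List of `partition_stats` from [nb_map()].
#' @param smoothing Laplace pseudocount (default 1).
#' @param feature_types Optional explicit types (`"binary"`/`"continuous"`
#'   per feature); by default binary means the feature only ever took values
#'   0/1 across all partitions, inferred from the statistics.
#' @return An `nb_model`.
#' @export
nb_reduce <- function(stats_list, smoothing = 1, feature_types = NULL) {
  merged <- merge_stats(stats_list)
  if (is.null(feature_types)) {
    # a 0/1 feature satisfies sum == sumsq exactly (x^2 == x for x in {0,1})
    feature_types <- ifelse(
      rowSums(merged$sum) == rowSums(merged$sumsq) &
        apply(merged$sum <= rep(merged$n, each = nrow(merged$sum)), 1, all),
      "binary", "continuous")
  }
  nb_model_from_stats(merged, feature_types, smoothing)
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> %d features (%d binary, %d continuous), priors: %s\n",
              length(x$feature_ids),
              sum(x$feature_types == "binary"),
              sum(x$feature_types == "continuous"),
              paste(sprintf("%s = %.3f", x$classes, x$priors), collapse = ", ")))
  invisible(x)
}

#' Predict with a naive Bayes model
#'
#' Posteriors are computed in log space (`log prior + sum of log
#' likelihoods`) and normalised per row; the label is the argmax, ties going
#' to the first class level.
#'
#' @param model An `nb_model`.
#' @param X Feature matrix with the model's feature count.
#' @return A list: `labels` (factor) and `posterior` (rows x classes matrix,
#'   rows summing to 1).
#' @export
nb_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_ids)) {
    abort(sprintf("Model has %d features, data has %d.",
                  length(model$feature_ids), ncol(X)),
          class = "combipath_error")
  }
  n <- nrow(X)
  logpost <- matrix(rep(log(model$priors), each = n), n, length(model$classes),
                    dimnames = list(NULL, model$classes))
  for (f in seq_along(model$feature_ids)) {
    x <- X[, f]
    for (ci in seq_along(model$classes)) {
      cl <- model$classes[ci]
      ll <- if (model$feature_types[f] == "binary") {
        p <- model$bernoulli[f, cl]
        x * log(p) + (1 - x) * log(1 - p)
      } else {
        stats::dnorm(x, mean = model$mean[f, cl],
                     sd = sqrt(model$var[f, cl]), log = TRUE)
      }
      logpost[, ci] <- logpost[, ci] + ll
    }
  }
  m <- apply(logpost, 1, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  labels <- factor(model$classes[max.col(post, ties.method = "first")],
                   levels = model$classes)
  list(labels = labels, posterior = post)
}

#' Trainer factories for the cross-validation protocols
#'
#' A trainer is a function taking a training [combination_dataset()] and
#' returning a prediction function (feature matrix in, factor labels out).
#' `svm_trainer()` and `nb_trainer()` wrap the two-class models;
#' `one_class_trainer()` trains on the rows of its input (intended for
#' positives-only datasets) and predicts `"effective"` for inliers.
#'
#' @param config A [kernel_config()] for the SVM.
#' @return A trainer function.
#' @export
svm_trainer <- function(config = kernel_config("gaussian")) {
  f <- function(train) {
    fit <- train_svm(train, config)
    function(X) predict(fit, X)
  }
  attr(f, "needs_both_classes") <- TRUE
  f
}

#' @rdname svm_trainer
#' @param smoothing Laplace pseudocount for [nb_fit()].
#' @export
nb_trainer <- function(smoothing = 1) {
  f <- function(train) {
    model <- nb_fit(train, smoothing = smoothing)
    function(X) nb_predict(model, X)$labels
  }
  attr(f, "needs_both_classes") <- TRUE
  f
}

#' @rdname svm_trainer
#' @param kind,g,nu Passed to [train_one_class_svm()].
#' @export
one_class_trainer <- function(kind = "gaussian", g = NULL, nu = 0.1) {
  f <- function(train) {
    gg <- g %||% (1 / ncol(train$X))
    fit <- train_one_class_svm(train$X, kind = kind, g = gg, nu = nu)
    function(X) {
      factor(ifelse(predict(fit, X), "effective", "noneffective"),
             levels = c("effective", "noneffective"))
    }
  }
  attr(f, "needs_both_classes") <- FALSE
  f
}

#' Tidy / glance methods for naive Bayes models
#'
#' @param x An `nb_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per feature x class with the fitted parameters;
#'   `glance()`: a one-row summary.
#' @export
tidy.nb_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$feature_ids), function(f) {
    purrr::map_dfr(x$classes, function(cl) {
      tibble(feature_id = x$feature_ids[f],
             class = cl,
             type = x$feature_types[f],
             bernoulli_p = x$bernoulli[f, cl],
             mean = x$mean[f, cl],
             variance = x$var[f, cl])
    })
  })
}

#' @rdname tidy.nb_model
#' @export
glance.nb_model <- function(x, ...) {
  tibble(n_features = length(x$feature_ids),
         n_binary = sum(x$feature_types == "binary"),
         n_continuous = sum(x$feature_types == "continuous"),
         smoothing = x$smoothing,
         prior_effective = unname(x$priors["effective"]))
}

#' Plain-text serialization of a naive Bayes model
#'
#' Versioned TSV-based format: a header block (`format`, `smoothing`,
#' `classes`, `priors`, `counts`) followed by one parameter row per feature
#' and class.
#'
#' @param model An `nb_model`.
#' @param path Output path.
#' @return `write_nb_model()`: `path`, invisibly; `read_nb_model()`: the
#'   restored `nb_model`.
#' @export
write_nb_model <- function(model, path) {
  writeLines(c(
    "#combipath_nb_model\tv1",
    paste0("#smoothing\t", format(model$smoothing, digits = 17)),
    paste0("#classes\t", paste(model$classes, collapse = "\t")),
    paste0("#priors\t", paste(format(model$priors, digits = 17), collapse = "\t")),
    paste0("#counts\t", paste(format(model$class_counts, digits = 17), collapse = "\t"))
  ), path)
  readr::write_tsv(tidy.nb_model(model), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- header[startsWith(header, paste0("#", key, "\t"))]
    strsplit(ln, "\t", fixed = TRUE)[[1]][-1]
  }
  if (!identical(get("combipath_nb_model"), "v1")) {
    abort("Unrecognised model file format.", class = "combipath_format_error")
  }
  classes <- get("classes")
  tbl <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         col_types = readr::cols(
                           feature_id = readr::col_character(),
                           class = readr::col_character(),
                           type = readr::col_character(),
                           .default = readr::col_double()))
  feature_ids <- unique(tbl$feature_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(feature_ids), length(classes),
                dimnames = list(feature_ids, classes))
    m[cbind(match(tbl$feature_id, feature_ids), match(tbl$class, classes))] <- tbl[[col]]
    m
  }
  types <- tbl$type[match(feature_ids, tbl$feature_id)]
  structure(
    list(classes = classes,
         priors = setNames(as.numeric(get("priors")), classes),
         feature_ids = feature_ids,
         feature_types = setNames(types, feature_ids),
         bernoulli = shape("bernoulli_p"),
         mean = shape("mean"),
         var = shape("variance"),
         smoothing = as.numeric(get("smoothing")),
         class_counts = setNames(as.numeric(get("counts")), classes)),
    class = "nb_model"
  )
}
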