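# Discretize a continuous feature into 3 bins split at mean +/- one sd
# (the classic mRMR convention); binary 0/1 features pass through untouched.
discretize_feature <- function(x) {
  ux <- unique(x)
  if (all(ux %in% c(0, 1))) return(as.integer(x))
  m <- mean(x); s <- sd(x)
  if (s == 0) return(rep(0L, length(x)))
  as.integer(cut(x, breaks = c(-Inf, m - s, m + s, Inf),
                 labels = FALSE, right = FALSE)) - 1L
}

# Mutual information (nats) between two discrete vectors, plug-in estimate.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  terms <- pxy * log(pxy / outer(px, py))
  sum(terms[pxy > 0])
}

#' Greedy mRMR feature selection
#'
#' Minimum-redundancy maximum-relevance forward selection (MID, the
#' difference variant): the first feature maximises the mutual information
#' I(f; y) with the label; each subsequent feature f maximises
#' `I(f; y) - mean_{s in selected} I(f; s)`.
#' Continuous features are discretised into 3 bins at mean +/- one standard
#' deviation before estimating mutual information; binary 0/1 features are
#' used as-is. Ties break to the lowest column index, making the trace fully
#' deterministic.
#'
#' @param dataset A [combination_dataset()].
#' @param k Number of features to select (0 <= k <= feature count).
#' @param variant `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return A `selection_result` tibble: `rank`, `feature_id`, `index`,
#'   `relevance`, `criterion` (the greedy objective at the step the feature
#'   was chosen).
#' @export
mrmr_select <- function(dataset, k, variant = c("MID", "MIQ")) {
  variant <- match.arg(variant)
  p <- ncol(dataset$X)
  if (k < 0 || k > p) {
    abort(sprintf("k must be in [0, %d].", p), class = "combipath_error")
  }
  disc <- apply(dataset$X, 2, discretize_feature)
  y <- dataset$y
  relevance <- apply(disc, 2, mutual_information, y = y)

  selected <- integer(0)
  criterion <- numeric(0)
  # cache pairwise feature MI lazily: mi_cache[s, f]
  mi_cache <- matrix(NA_real_, nrow = p, ncol = p)
  while (length(selected) < k) {
    remaining <- setdiff(seq_len(p), selected)
    if (length(selected) == 0L) {
      obj <- relevance[remaining]
    } else {
      red <- vapply(remaining, function(f) {
        vals <- vapply(selected, function(s) {
          if (is.na(mi_cache[s, f])) {
            mi_cache[s, f] <<- mutual_information(disc[, s], disc[, f])
          }
          mi_cache[s, f]
        }, numeric(1))
        mean(vals)
      }, numeric(1))
      obj <- if (variant == "MID") relevance[remaining] - red
             else relevance[remaining] / (red + 1e-12)
    }
    best <- remaining[which.max(obj)]  # which.max -> first (lowest index) on ties
    selected <- c(selected, best)
    criterion <- c(criterion, max(obj))
  }
  res <- tibble(
    rank = seq_along(selected),
    feature_id = dataset$feature_ids[selected],
    index = selected,
    relevance = unname(relevance[selected]),
    criterion = criterion
  )
  class(res) <- c("selection_result", class(res))
  res
}

#' Default feature count: one quarter of the sample count
#'
#' The rule of thumb used to keep the model complexity proportionate to a
#' small sample: select `floor(n_samples / 4)` features.
#'
#' @param n_samples Total sample count (>= 4, so at least one feature results).
#' @return Integer feature count.
#' @examples
#' default_feature_count(152)  # 38
#' @export
default_feature_count <- function(n_samples) {
  if (n_samples < 4) {
    abort("Need at least 4 samples for the one-quarter rule.",
          class = "combipath_error")
  }
  as.integer(floor(n_samples / 4))
}

#' Select the top-scoring frequent patterns
#'
#' Orders patterns by decreasing frequency score S, breaking ties by higher
#' effective-set count `n_ec` and then lexicographic pattern id, and keeps the
#' first `k`.
#'
#' @param table A `pattern_table` (see [frequency_scores()]).
#' @param k Number of patterns to keep (<= pattern count).
#' @return A `selection_result` tibble: `rank`, `feature_id`, `index` (row in
#'   the sorted table), `criterion` (the score), plus the `i`, `j` pattern
#'   indices so the result can feed [build_dataset()] directly.
#' @export
select_frequent_patterns <- function(table, k) {
  if (k > nrow(table)) {
    abort(sprintf("k = %d exceeds the %d available patterns.", k, nrow(table)),
          class = "combipath_error")
  }
  ord <- order(-table$score, -table$n_ec, table$pattern)
  top <- table[ord[seq_len(k)], , drop = FALSE]
  res <- tibble(
    rank = seq_len(k),
    feature_id = top$pattern,
    index = ord[seq_len(k)],
    criterion = top$score,
    i = top$i,
    j = top$j
  )
  class(res) <- c("selection_result", class(res))
  res
}

#' Write a selection result as TSV
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  readr::write_tsv(as_tibble(as.data.frame(result)), path)
  invisible(path)
}
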