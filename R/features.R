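#' Canonicalise a table of drug pairs
#'
#' Pairs are unordered; the canonical storage sorts the two ids
#' lexicographically into `drug_a` < `drug_b`. Self-pairs and duplicates are
#' rejected.
#'
#' @param pairs A data frame with character columns `drug_a`, `drug_b`.
#' @return A tibble with canonical `drug_a`, `drug_b` columns (other columns
#'   preserved).
#' @export
canonical_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("drug_a", "drug_b") %in% names(pairs))) {
    abort("`pairs` needs columns drug_a and drug_b.", class = "combipath_error")
  }
  if (any(pairs$drug_a == pairs$drug_b)) {
    abort("Self-pairs are not valid drug combinations.", class = "combipath_error")
  }
  a <- pmin(pairs$drug_a, pairs$drug_b)
  b <- pmax(pairs$drug_a, pairs$drug_b)
  out <- dplyr::mutate(pairs, drug_a = a, drug_b = b)
  if (anyDuplicated(paste(out$drug_a, out$drug_b))) {
    abort("Duplicate drug pairs after canonicalisation.", class = "combipath_error")
  }
  out
}

pair_keys <- function(pairs) paste(pairs$drug_a, pairs$drug_b, sep = "+")

#' Read / write a drug-pair list
#'
#' Two-column TSV (`drug_a`, `drug_b`) with an optional third `label` column
#' (`effective` / `noneffective`).
#'
#' @param path File path.
#' @return `read_pairs()`: a canonicalised tibble. `write_pairs()`: `path`,
#'   invisibly.
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  canonical_pairs(df)
}

#' @rdname read_pairs
#' @param pairs Tibble of pairs.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' Linear-addition combination feature over shared genes
#'
#' Encodes the joint effect of a drug pair on each gene shared by the two
#' studies as the sum of the two drugs' centred control/treated expression
#' ratios: for gene G,
#' `(P1/C1 - 1) + (P2/C2 - 1)`,
#' where P is the mean control (unaffected) and C the mean treated (affected)
#' expression of that drug's study. A gene untouched by both drugs scores 0;
#' the encoding is symmetric in the two drugs. The default orientation keeps
#' control over treated; `orientation = "treated_over_control"` flips each
#' ratio to the conventional fold-change direction.
#'
#' @param study_a,study_b [expression_study()] objects sharing >= 1 gene.
#' @param orientation Ratio orientation, see Details.
#' @return Named numeric vector over the sorted shared gene ids.
#' @examples
#' a <- expression_study("a", "G1", matrix(5), matrix(10))
#' b <- expression_study("b", "G1", matrix(3), matrix(6))
#' linear_addition_feature(a, b)  # (10/5 - 1) + (6/3 - 1) = 2
#' @export
linear_addition_feature <- function(study_a, study_b,
                                    orientation = c("control_over_treated",
                                                    "treated_over_control")) {
  orientation <- match.arg(orientation)
  shared <- sort(intersect(study_a$gene_ids, study_b$gene_ids))
  if (length(shared) == 0L) {
    abort("Studies share no genes.", class = "combipath_error")
  }
  term <- function(study) {
    p <- rowMeans(study$control)[shared]
    c_ <- rowMeans(study$treated)[shared]
    if (orientation == "control_over_treated") p / c_ - 1 else c_ / p - 1
  }
  term(study_a) + term(study_b)
}

#' Pathway-pair patterns realised by a drug pair
#'
#' A pattern is an unordered pair of pathway indices \{i, j\} such that one
#' drug of the combination affects pathway i and the other affects pathway j
#' (i = j when both drugs affect the same pathway). The result is symmetric in
#' the two vectors.
#'
#' @param vec_a,vec_b `pathway_vector` objects (or plain 0/1 vectors) of equal
#'   length.
#' @return Integer matrix with columns `i`, `j` (i <= j), one unique pattern
#'   per row, ordered by (i, j).
#' @export
extract_patterns <- function(vec_a, vec_b) {
  a <- if (inherits(vec_a, "pathway_vector")) vec_a$bits else vec_a
  b <- if (inherits(vec_b, "pathway_vector")) vec_b$bits else vec_b
  if (length(a) != length(b)) {
    abort("Pathway vectors differ in length.", class = "combipath_error")
  }
  ia <- which(a == 1L)
  ib <- which(b == 1L)
  if (length(ia) == 0L || length(ib) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  grid <- expand.grid(i = ia, j = ib)
  pat <- cbind(i = pmin(grid$i, grid$j), j = pmax(grid$i, grid$j))
  pat <- unique(pat)
  pat <- pat[order(pat[, 1], pat[, 2]), , drop = FALSE]
  rownames(pat) <- NULL
  pat
}

pattern_id <- function(i, j) paste(i, j, sep = ":")

#' Frequency scores of pathway-pair patterns
#'
#' Counts how often each pathway-pair pattern occurs among the known effective
#' combinations (`n_ec`) and among random re-pairings of the same drugs
#' (`n_rc`, scaled to the effective-set size so the two counts are
#' commensurable), and scores each pattern as
#' `S = n_ec / (n_rc + pseudocount)`.
#' High S marks patterns enriched in effective combinations relative to the
#' random-pairing background.
#'
#' @param effective Tibble of effective pairs (`drug_a`, `drug_b`).
#' @param vectors Named list of `pathway_vector`s covering every drug in
#'   `effective` (extra drugs enlarge the random-pairing universe).
#' @param n_random Number of random pairs drawn for the background (default
#'   10 x the effective count).
#' @param pseudocount Added to the scaled background count before dividing
#'   (default 1); keeps scores finite for patterns unseen in the background.
#' @param seed Integer seed for the background draw.
#' @param include_diagonal Keep \{i, i\} patterns (default `TRUE`).
#' @return A `pattern_table` tibble: `pattern`, `pathway_i`, `pathway_j`,
#'   `i`, `j`, `n_ec`, `n_rc`, `score`, sorted by decreasing score.
#' @export
frequency_scores <- function(effective, vectors,
                             n_random = 10L * nrow(effective),
                             pseudocount = 1, seed = 1L,
                             include_diagonal = TRUE) {
  effective <- canonical_pairs(effective)
  if (nrow(effective) == 0L) {
    abort("Need at least one effective pair.", class = "combipath_error")
  }
  if (n_random < 1L) {
    abort("`n_random` must be >= 1.", class = "combipath_error")
  }
  drugs_needed <- unique(c(effective$drug_a, effective$drug_b))
  missing <- setdiff(drugs_needed, names(vectors))
  if (length(missing) > 0L) {
    abort(sprintf("No pathway vector for drug(s): %s",
                  paste(missing, collapse = ", ")),
          class = "combipath_error")
  }
  universe <- names(vectors)

  count_patterns <- function(pair_df) {
    pats <- purrr::map2(pair_df$drug_a, pair_df$drug_b, function(a, b) {
      m <- extract_patterns(vectors[[a]], vectors[[b]])
      pattern_id(m[, "i"], m[, "j"])
    })
    table(unlist(pats))
  }

  ec_counts <- count_patterns(effective)

  rc_pairs <- withr::with_seed(seed, {
    a <- character(n_random)
    b <- character(n_random)
    for (r in seq_len(n_random)) {
      pick <- sample(universe, 2L, replace = FALSE)
      a[r] <- min(pick); b[r] <- max(pick)
    }
    tibble(drug_a = a, drug_b = b)
  })
  rc_counts_raw <- count_patterns(rc_pairs)

  all_ids <- union(names(ec_counts), names(rc_counts_raw))
  if (length(all_ids) == 0L) {
    abort("No pattern realised by any pair; are all pathway vectors zero?",
          class = "combipath_error")
  }
  n_ec <- as.numeric(ec_counts[all_ids]); n_ec[is.na(n_ec)] <- 0
  n_rc <- as.numeric(rc_counts_raw[all_ids]); n_rc[is.na(n_rc)] <- 0
  n_rc <- n_rc * nrow(effective) / n_random

  idx <- do.call(rbind, strsplit(all_ids, ":", fixed = TRUE))
  i <- as.integer(idx[, 1]); j <- as.integer(idx[, 2])
  pw_ids <- names(vectors[[1]]$bits) %||% as.character(seq_len(max(j)))

  tbl <- tibble(
    pattern = all_ids,
    pathway_i = pw_ids[i],
    pathway_j = pw_ids[j],
    i = i, j = j,
    n_ec = n_ec,
    n_rc = n_rc,
    score = n_ec / (n_rc + pseudocount)
  )
  if (!include_diagonal) tbl <- dplyr::filter(tbl, .data$i != .data$j)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$score), dplyr::desc(.data$n_ec),
                        .data$pattern)
  class(tbl) <- c("pattern_table", class(tbl))
  attr(tbl, "n_effective") <- nrow(effective)
  attr(tbl, "n_random") <- n_random
  attr(tbl, "pseudocount") <- pseudocount
  tbl
}

#' Read / write a pattern table
#'
#' TSV with columns `pattern`, `pathway_i`, `pathway_j`, `i`, `j`, `n_ec`,
#' `n_rc`, `score`.
#'
#' @param path File path.
#' @return `read_pattern_table()`: a `pattern_table` tibble;
#'   `write_pattern_table()`: `path`, invisibly.
#' @export
read_pattern_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    pattern = readr::col_character(),
    pathway_i = readr::col_character(),
    pathway_j = readr::col_character(),
    i = readr::col_integer(),
    j = readr::col_integer(),
    .default = readr::col_double()
  ))
  class(tbl) <- c("pattern_table", class(tbl))
  tbl
}

#' @rdname read_pattern_table
#' @param table A `pattern_table`.
#' @export
write_pattern_table <- function(table, path) {
  readr::write_tsv(as_tibble(as.data.frame(table)), path)
  invisible(path)
}

#' Combination dataset: feature matrix plus labels for drug pairs
#'
#' @param pairs Canonical tibble of drug pairs (one row per sample).
#' @param X Numeric feature matrix, one row per pair.
#' @param y Labels, coerced to a factor with levels
#'   `c("effective", "noneffective")`.
#' @param feature_ids Column names for `X`.
#' @param representation `"linear_addition"` or `"frequent_pattern"`.
#' @return An object of class `combination_dataset`.
#' @export
combination_dataset <- function(pairs, X, y, feature_ids = colnames(X),
                                representation = "custom") {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("effective", "noneffective"))
  if (nrow(pairs) != nrow(X) || nrow(X) != length(y)) {
    abort("Rows of pairs, X and labels must align.", class = "combipath_error")
  }
  if (anyNA(y)) {
    abort("Labels must be 'effective' or 'noneffective'.", class = "combipath_error")
  }
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(X)))
  colnames(X) <- feature_ids
  rownames(X) <- pair_keys(pairs)
  structure(
    list(pairs = as_tibble(pairs[, c("drug_a", "drug_b")]),
         X = X, y = y,
         feature_ids = feature_ids,
         representation = representation),
    class = "combination_dataset"
  )
}

#' @export
print.combination_dataset <- function(x, ...) {
  cat(sprintf("<combination_dataset> %d pairs x %d features (%s); %d effective / %d noneffective\n",
              nrow(x$X), ncol(x$X), x$representation,
              sum(x$y == "effective"), sum(x$y == "noneffective")))
  invisible(x)
}

#' Tidy a combination dataset
#'
#' @param x A [combination_dataset()].
#' @param ... Unused.
#' @return A tibble: pair columns, `label`, then one column per feature.
#' @export
tidy.combination_dataset <- function(x, ...) {
  dplyr::bind_cols(x$pairs, tibble(label = x$y), as_tibble(x$X))
}

#' Subset a combination dataset by row
#'
#' @param dataset A [combination_dataset()].
#' @param idx Integer or logical row index.
#' @return A [combination_dataset()] over the selected pairs.
#' @export
subset_dataset <- function(dataset, idx) {
  combination_dataset(dataset$pairs[idx, , drop = FALSE],
                      dataset$X[idx, , drop = FALSE],
                      dataset$y[idx],
                      feature_ids = dataset$feature_ids,
                      representation = dataset$representation)
}

#' Build a combination dataset under either feature representation
#'
#' `linear_addition`: one continuous column per gene shared by every involved
#' study, holding the pair's [linear_addition_feature()] value.
#' `frequent_pattern`: one binary column per selected pattern, 1 when the
#' pair's [extract_patterns()] output contains the pattern.
#'
#' @param pairs Tibble with `drug_a`, `drug_b` and a `label` column
#'   (`effective` / `noneffective`), or pass labels separately via `labels`.
#' @param representation `"linear_addition"` or `"frequent_pattern"`.
#' @param studies Named list of studies (linear_addition).
#' @param vectors Named list of `pathway_vector`s (frequent_pattern).
#' @param patterns Pattern context for frequent_pattern: a `pattern_table`
#'   (all its rows are used, so pre-filter with [select_frequent_patterns()])
#'   or an integer matrix with columns `i`, `j`.
#' @param labels Optional label vector overriding `pairs$label`.
#' @param orientation Passed to [linear_addition_feature()].
#' @return A [combination_dataset()].
#' @export
build_dataset <- function(pairs,
                          representation = c("linear_addition", "frequent_pattern"),
                          studies = NULL, vectors = NULL, patterns = NULL,
                          labels = NULL,
                          orientation = "control_over_treated") {
  representation <- match.arg(representation)
  pairs <- canonical_pairs(pairs)
  if (nrow(pairs) == 0L) {
    abort("No pairs to build a dataset from.", class = "combipath_error")
  }
  y <- labels %||% pairs$label
  if (is.null(y)) {
    abort("Labels required: a `label` column or the `labels` argument.",
          class = "combipath_error")
  }

  if (representation == "linear_addition") {
    if (is.null(studies)) {
      abort("linear_addition needs `studies`.", class = "combipath_error")
    }
    involved <- unique(c(pairs$drug_a, pairs$drug_b))
    missing <- setdiff(involved, names(studies))
    if (length(missing) > 0L) {
      abort(sprintf("No study for drug(s): %s", paste(missing, collapse = ", ")),
            class = "combipath_error")
    }
    shared <- sort(Reduce(intersect, purrr::map(studies[involved], "gene_ids")))
    if (length(shared) == 0L) {
      abort("Involved studies share no genes.", class = "combipath_error")
    }
    rows <- purrr::map2(pairs$drug_a, pairs$drug_b, function(a, b) {
      v <- linear_addition_feature(studies[[a]], studies[[b]],
                                   orientation = orientation)
      unname(v[shared])
    })
    X <- do.call(rbind, rows)
    dimnames(X) <- list(NULL, shared)
    return(combination_dataset(pairs, X, y, feature_ids = shared,
                               representation = "linear_addition"))
  }

  if (is.null(vectors) || is.null(patterns)) {
    abort("frequent_pattern needs `vectors` and `patterns`.",
          class = "combipath_error")
  }
  if (inherits(patterns, "pattern_table") || is.data.frame(patterns)) {
    pat <- cbind(i = patterns$i, j = patterns$j)
  } else {
    pat <- patterns[, c("i", "j"), drop = FALSE]
  }
  ids <- pattern_id(pat[, "i"], pat[, "j"])
  rows <- purrr::map2(pairs$drug_a, pairs$drug_b, function(a, b) {
    m <- extract_patterns(vectors[[a]], vectors[[b]])
    have <- pattern_id(m[, "i"], m[, "j"])
    as.integer(ids %in% have)
  })
  X <- do.call(rbind, rows)
  dimnames(X) <- list(NULL, ids)
  combination_dataset(pairs, X, y, feature_ids = ids,
                      representation = "frequent_pattern")
}

#' Generate noneffective (negative) drug pairs
#'
#' Draws `n` distinct unordered pairs from the drugs appearing in the positive
#' set, excluding the positives themselves and self-pairs. By default the
#' negative set is the same size as the positive set, giving a balanced
#' two-class dataset.
#'
#' @param positives Tibble of effective pairs (`drug_a`, `drug_b`).
#' @param n Number of negatives (default `nrow(positives)`).
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return Tibble of `n` canonical pairs, disjoint from `positives`.
#' @export
generate_negative_pairs <- function(positives, n = nrow(positives), seed = 1L) {
  positives <- canonical_pairs(positives)
  universe <- sort(unique(c(positives$drug_a, positives$drug_b)))
  if (length(universe) < 2L) {
    abort("Need at least two distinct drugs.", class = "combipath_error")
  }
  all_pairs <- t(combn(universe, 2L))
  keys <- paste(all_pairs[, 1], all_pairs[, 2], sep = "+")
  candidate <- !(keys %in% pair_keys(positives))
  if (n > sum(candidate)) {
    abort(sprintf("Requested %d negatives but only %d non-positive pairs exist.",
                  n, sum(candidate)),
          class = "combipath_error")
  }
  pick <- withr::with_seed(seed, sample(which(candidate), n, replace = FALSE))
  tibble(drug_a = all_pairs[pick, 1], drug_b = all_pairs[pick, 2])
}
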