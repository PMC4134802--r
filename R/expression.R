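#' Per-drug expression study
#'
#' An `expression_study` holds the treated and control replicate arrays for a
#' single drug perturbation: a genes x replicates matrix per arm, sharing one
#' gene order. Expression values are post-normalization intensities and must be
#' strictly positive (fold-change style features divide by them).
#'
#' @param drug_id Drug identifier (length-1 character).
#' @param gene_ids Character vector of gene identifiers, one per matrix row.
#' @param treated,control Numeric matrices, genes x replicates, all values > 0.
#'
#' @return An object of class `expression_study`.
#' @examples
#' tr <- matrix(c(10, 20, 11, 19), nrow = 2)
#' ct <- matrix(c(5, 21, 6, 20), nrow = 2)
#' expression_study("drugA", c("G1", "G2"), tr, ct)
#' @export
expression_study <- function(drug_id, gene_ids, treated, control) {
  treated <- as.matrix(treated)
  control <- as.matrix(control)
  if (length(drug_id) != 1L || !nzchar(drug_id)) {
    abort("`drug_id` must be a single non-empty string.", class = "combipath_error")
  }
  if (nrow(treated) != length(gene_ids) || nrow(control) != length(gene_ids)) {
    abort("`treated` and `control` must have one row per gene id.",
          class = "combipath_error")
  }
  if (ncol(treated) < 1L || ncol(control) < 1L) {
    abort("Each arm needs at least one replicate column.", class = "combipath_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort("Duplicated gene ids in expression study.", class = "combipath_error")
  }
  if (!is.numeric(treated) || !is.numeric(control) ||
      anyNA(treated) || anyNA(control) ||
      any(treated <= 0) || any(control <= 0)) {
    abort("Expression values must be finite and strictly positive.",
          class = "combipath_error")
  }
  rownames(treated) <- rownames(control) <- gene_ids
  structure(
    list(drug_id = as.character(drug_id),
         gene_ids = as.character(gene_ids),
         treated = treated,
         control = control),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> drug %s: %d genes, %d treated / %d control replicates\n",
              x$drug_id, length(x$gene_ids), ncol(x$treated), ncol(x$control)))
  invisible(x)
}

#' @describeIn expression_study number of genes.
#' @param x An `expression_study`.
#' @param ... Unused.
#' @export
n_genes <- function(x, ...) length(x$gene_ids)

#' Tidy an expression study into long format
#'
#' @param x An `expression_study`.
#' @param ... Unused.
#' @return A tibble with columns `drug_id`, `gene_id`, `arm`, `replicate`,
#'   `expression`.
#' @export
tidy.expression_study <- function(x, ...) {
  arm_tbl <- function(mat, arm) {
    tibble(
      drug_id = x$drug_id,
      gene_id = rep(x$gene_ids, times = ncol(mat)),
      arm = arm,
      replicate = rep(seq_len(ncol(mat)), each = nrow(mat)),
      expression = as.vector(mat)
    )
  }
  dplyr::bind_rows(arm_tbl(x$treated, "treated"), arm_tbl(x$control, "control"))
}

#' Read a per-drug expression table
#'
#' Expects a TSV whose first column is headed `gene_id` and whose remaining
#' columns are headed `treated_<k>` or `control_<k>`. This is the one-file-per-
#' drug layout listed in a study manifest (see [read_manifest()]).
#'
#' @param path Path to the TSV file.
#' @param drug_id Drug identifier to attach to the study.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(path, drug_id) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!identical(names(df)[1], "gene_id")) {
    abort(sprintf("First column of %s must be headed 'gene_id'.", path),
          class = "combipath_format_error")
  }
  value_cols <- names(df)[-1]
  is_tr <- grepl("^treated_[0-9]+$", value_cols)
  is_ct <- grepl("^control_[0-9]+$", value_cols)
  if (any(!is_tr & !is_ct)) {
    abort(sprintf("Columns of %s must be headed treated_<k>/control_<k>; found: %s",
                  path, paste(value_cols[!is_tr & !is_ct], collapse = ", ")),
          class = "combipath_format_error")
  }
  if (!any(is_tr) || !any(is_ct)) {
    abort(sprintf("%s must contain at least one treated and one control column.", path),
          class = "combipath_format_error")
  }
  if (anyNA(df)) {
    abort(sprintf("Non-numeric or missing cells in %s.", path),
          class = "combipath_parse_error")
  }
  expression_study(
    drug_id = drug_id,
    gene_ids = df$gene_id,
    treated = as.matrix(df[, value_cols[is_tr], drop = FALSE]),
    control = as.matrix(df[, value_cols[is_ct], drop = FALSE])
  )
}

#' Write a per-drug expression table
#'
#' Inverse of [read_expression_study()].
#'
#' @param study An [expression_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_study <- function(study, path) {
  tr <- as.data.frame(study$treated)
  names(tr) <- paste0("treated_", seq_len(ncol(tr)))
  ct <- as.data.frame(study$control)
  names(ct) <- paste0("control_", seq_len(ncol(ct)))
  out <- dplyr::bind_cols(tibble(gene_id = study$gene_ids), tr, ct)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a study-collection manifest
#'
#' A manifest is a two-column TSV (`drug_id`, `path`) listing one expression
#' file per drug. Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return A named list of [expression_study()] objects, keyed by drug id.
#' @export
read_manifest <- function(path) {
  mf <- readr::read_tsv(path, col_types = readr::cols(
    drug_id = readr::col_character(), path = readr::col_character()
  ))
  if (anyDuplicated(mf$drug_id)) {
    abort("Duplicate drug ids in manifest.", class = "combipath_format_error")
  }
  base <- dirname(path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  studies <- purrr::map2(mf$path, mf$drug_id,
                         function(p, d) read_expression_study(resolve(p), d))
  setNames(studies, mf$drug_id)
}

#' Filter a study by replicate count
#'
#' Studies whose arms do not both reach `min_replicates` columns are flagged as
#' excluded rather than erroring: exclusion is a normal quality-control outcome
#' when harmonising a heterogeneous compendium. The default of 3 reflects the
#' usual minimum for a two-sample test with any power.
#'
#' @param study An [expression_study()].
#' @param min_replicates Minimum replicate count per arm (default 3).
#' @return A list with elements `study` (unchanged) and `retained` (logical).
#' @export
filter_by_replicates <- function(study, min_replicates = 3L) {
  if (min_replicates < 1L) {
    abort("`min_replicates` must be >= 1.", class = "combipath_error")
  }
  keep <- ncol(study$treated) >= min_replicates && ncol(study$control) >= min_replicates
  list(study = study, retained = keep)
}

#' Filter a collection of studies by replicate count
#'
#' @param studies Named list of [expression_study()] objects.
#' @inheritParams filter_by_replicates
#' @return Named list containing only the retained studies.
#' @export
filter_studies <- function(studies, min_replicates = 3L) {
  kept <- purrr::keep(studies, function(s) filter_by_replicates(s, min_replicates)$retained)
  kept
}

# Vectorised pooled-variance (or Welch) two-sample t-test across matrix rows.
# Returns a tibble of per-gene statistics; genes with zero variance in both
# arms get p = 1 by convention (flat genes are never called significant).
row_t_test <- function(treated, control, var_equal = TRUE) {
  n1 <- ncol(treated)
  n2 <- ncol(control)
  m1 <- rowMeans(treated)
  m2 <- rowMeans(control)
  v1 <- rowSums((treated - m1)^2) / (n1 - 1)
  v2 <- rowSums((control - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  flat <- v1 == 0 & v2 == 0
  p[flat] <- 1
  stat[flat] <- 0
  tibble(gene_id = rownames(treated), statistic = unname(stat), df = unname(df),
         p_value = unname(p), mean_treated = unname(m1), mean_control = unname(m2))
}

#' Call a drug's significantly changed gene set
#'
#' Runs a two-sample Student's t-test (pooled variance by default; Welch via
#' `var_equal = FALSE`) per gene between the treated and control arms and
#' returns the genes with raw p-value below `alpha`. No multiple-testing
#' correction is applied: the signature feeds a set-intersection pathway
#' mapping, not per-gene inference. Genes flat in both arms are assigned
#' p = 1 rather than propagating NaN.
#'
#' @param study An [expression_study()]; both arms need >= 2 replicates.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param var_equal Pooled-variance Student's test if `TRUE` (default), Welch
#'   otherwise.
#' @return A `drug_signature`: list with `drug_id`, `significant_genes`
#'   (character vector), `alpha`, and a `stats` tibble of per-gene results.
#' @examples
#' tr <- matrix(rep(c(10, 10.5, 9.5), each = 1), nrow = 1)
#' ct <- matrix(c(1, 1.1, 0.9), nrow = 1)
#' s <- expression_study("d", "G1", tr, ct)
#' differential_genes(s, alpha = 0.05)$significant_genes
#' @export
differential_genes <- function(study, alpha = 0.05, var_equal = TRUE) {
  if (ncol(study$treated) < 2L || ncol(study$control) < 2L) {
    abort("Both arms need >= 2 replicates for a t-test.",
          class = "combipath_precondition_error")
  }
  if (!(alpha > 0 && alpha <= 1)) {
    abort("`alpha` must be in (0, 1].", class = "combipath_error")
  }
  res <- row_t_test(study$treated, study$control, var_equal = var_equal)
  sig <- res$gene_id[res$p_value < alpha]
  structure(
    list(drug_id = study$drug_id,
         significant_genes = sig,
         alpha = alpha,
         stats = res),
    class = "drug_signature"
  )
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("<drug_signature> drug %s: %d significant genes at alpha = %g\n",
              x$drug_id, length(x$significant_genes), x$alpha))
  invisible(x)
}

#' Tidy a drug signature
#'
#' @param x A `drug_signature`.
#' @param ... Unused.
#' @return The per-gene t-test tibble with a logical `significant` column.
#' @export
tidy.drug_signature <- function(x, ...) {
  dplyr::mutate(x$stats,
                drug_id = x$drug_id,
                significant = .data$p_value < x$alpha,
                .before = 1)
}
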