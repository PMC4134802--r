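#' Pathway gene-set collection
#'
#' Light container over an ordered list of named gene sets, as distributed in
#' GMT format (e.g. the MSigDB disease-pathway collections). Gene symbols are
#' stored upper-cased so that membership tests are robust to the mixed casing
#' of microarray annotation sources.
#'
#' @param pathway_ids Character vector of unique pathway names.
#' @param gene_sets List of character vectors, one non-empty set per pathway.
#' @param descriptions Optional character vector (GMT column 2); retained but
#'   unused downstream.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathway_ids, gene_sets, descriptions = NULL) {
  if (length(pathway_ids) != length(gene_sets)) {
    abort("One gene set per pathway id required.", class = "combipath_error")
  }
  if (anyDuplicated(pathway_ids)) {
    abort("Duplicate pathway ids.", class = "combipath_format_error")
  }
  if (any(lengths(gene_sets) == 0L)) {
    abort("Every pathway gene set must be non-empty.", class = "combipath_format_error")
  }
  gene_sets <- purrr::map(gene_sets, function(g) unique(toupper(as.character(g))))
  structure(
    list(pathway_ids = as.character(pathway_ids),
         gene_sets = setNames(gene_sets, pathway_ids),
         descriptions = descriptions %||% rep("", length(pathway_ids))),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, %d..%d genes each\n",
              length(x$pathway_ids),
              min(lengths(x$gene_sets)), max(lengths(x$gene_sets))))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathway_ids)

#' Tidy a pathway collection into long (pathway, gene) pairs
#'
#' @param x A [pathway_collection()].
#' @param ... Unused.
#' @return A tibble with columns `pathway_id`, `gene_id`.
#' @export
tidy.pathway_collection <- function(x, ...) {
  tibble(
    pathway_id = rep(x$pathway_ids, times = lengths(x$gene_sets)),
    gene_id = unlist(x$gene_sets, use.names = FALSE)
  )
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB dialect: one set per line, `name TAB description TAB gene
#' TAB gene ...`. File order is preserved; lines with fewer than three fields
#' or duplicated set names are format errors.
#'
#' @param path Path to the GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("GMT file %s is empty.", path), class = "combipath_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", which(bad)[1]),
          class = "combipath_format_error")
  }
  ids <- purrr::map_chr(fields, 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated pathway name in %s: %s", path,
                  ids[duplicated(ids)][1]),
          class = "combipath_format_error")
  }
  pathway_collection(
    pathway_ids = ids,
    gene_sets = purrr::map(fields, function(f) f[-(1:2)]),
    descriptions = purrr::map_chr(fields, 2)
  )
}

#' Write gene sets to a GMT file
#'
#' @param collection A [pathway_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::imap_chr(collection$gene_sets, function(genes, id) {
    desc <- collection$descriptions[match(id, collection$pathway_ids)]
    paste(c(id, desc, genes), collapse = "\t")
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' Map a drug signature to a binary pathway-affect vector
#'
#' A pathway is "affected" by a drug when at least one of the drug's
#' significantly changed genes falls in the pathway's gene set — an
#' existential criterion, not an enrichment test. Matching is exact string
#' match after upper-casing.
#'
#' @param signature A `drug_signature` (see [differential_genes()]), or any
#'   list with `drug_id` and `significant_genes`.
#' @param pathways A [pathway_collection()].
#' @return A `pathway_vector`: list with `drug_id` and `bits`, a named 0/1
#'   integer vector ordered as the collection.
#' @examples
#' pc <- pathway_collection(c("P1", "P2"), list(c("g1", "g2"), "g3"))
#' sig <- list(drug_id = "d", significant_genes = "g1")
#' affected_pathways(sig, pc)$bits
#' @export
affected_pathways <- function(signature, pathways) {
  genes <- toupper(signature$significant_genes)
  bits <- purrr::map_int(pathways$gene_sets,
                         function(gs) as.integer(any(genes %in% gs)))
  structure(
    list(drug_id = signature$drug_id,
         bits = setNames(bits, pathways$pathway_ids)),
    class = "pathway_vector"
  )
}

#' @export
print.pathway_vector <- function(x, ...) {
  cat(sprintf("<pathway_vector> drug %s: %d/%d pathways affected\n",
              x$drug_id, sum(x$bits), length(x$bits)))
  invisible(x)
}

#' Pathway-affect vectors for a set of drugs
#'
#' Convenience wrapper: runs [differential_genes()] and [affected_pathways()]
#' over a study collection.
#'
#' @param studies Named list of [expression_study()] objects.
#' @param pathways A [pathway_collection()].
#' @inheritParams differential_genes
#' @return Named list of `pathway_vector` objects keyed by drug id.
#' @export
pathway_fingerprints <- function(studies, pathways, alpha = 0.05, var_equal = TRUE) {
  purrr::map(studies, function(s) {
    affected_pathways(differential_genes(s, alpha = alpha, var_equal = var_equal),
                      pathways)
  })
}
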