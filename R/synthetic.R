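#' Configuration for the synthetic study generator
#'
#' Defines a desk-scale in-silico compendium with fully known ground truth:
#' drugs with true affected pathways, replicated positive-valued expression
#' with genes truly shifted under treatment, pathway gene sets, and an
#' effective-pair list whose combinations co-realise planted pathway-pair
#' patterns. Baseline expression is lognormal (positive support with the
#' right-skew typical of microarray intensities); treatment shifts truly
#' changed genes multiplicatively by `exp(effect_size)`. `effect_size` and
#' `noise_sd` are both on the log scale, so their ratio is the per-replicate
#' signal-to-noise of a shifted gene.
#'
#' @param n_drugs Number of drugs (default 40).
#' @param n_genes Number of genes (default 500).
#' @param n_pathways Number of pathways (default 20).
#' @param genes_per_pathway Genes per pathway gene set (default 25).
#' @param replicates Replicates per arm (default 3).
#' @param n_effective_pairs Number of effective combinations (default 20).
#' @param planted_patterns List of length-2 integer vectors: the pathway-pair
#'   patterns that characterise effective combinations (default five disjoint
#'   pairs, so each pattern recurs across several effective combinations
#'   while accidental co-realisation by random re-pairings stays rare).
#' @param effect_size Mean log-fold shift of truly changed genes (default 1,
#'   i.e. 5 noise standard deviations).
#' @param noise_sd Replicate noise standard deviation on the log scale
#'   (default 0.2).
#' @param background_affect_rate Probability that a drug affects any given
#'   pathway for reasons unrelated to the planted structure (default 0.05,
#'   the sparse fingerprint typical of a focused perturbation).
#' @param seed Integer seed; the whole generation is deterministic given the
#'   config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 40L, n_genes = 500L, n_pathways = 20L,
                             genes_per_pathway = 25L, replicates = 3L,
                             n_effective_pairs = 20L,
                             planted_patterns = list(c(1L, 2L), c(3L, 4L), c(5L, 6L),
                                                     c(7L, 8L), c(9L, 10L)),
                             effect_size = 1, noise_sd = 0.2,
                             background_affect_rate = 0.05, seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              genes_per_pathway = as.integer(genes_per_pathway),
              replicates = as.integer(replicates),
              n_effective_pairs = as.integer(n_effective_pairs),
              planted_patterns = purrr::map(planted_patterns, as.integer),
              effect_size = effect_size, noise_sd = noise_sd,
              background_affect_rate = background_affect_rate,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_drugs, n_genes, n_pathways, genes_per_pathway, replicates,
              n_effective_pairs) < 1L)) {
      abort("All counts must be >= 1.", class = "combipath_error")
    }
    if (effect_size < 0) {
      abort("`effect_size` must be >= 0.", class = "combipath_error")
    }
    if (noise_sd <= 0) {
      abort("`noise_sd` must be > 0.", class = "combipath_error")
    }
    if (!(background_affect_rate >= 0 && background_affect_rate < 1)) {
      abort("`background_affect_rate` must be in [0, 1).", class = "combipath_error")
    }
    if (any(unlist(planted_patterns) > n_pathways) ||
        any(unlist(planted_patterns) < 1L) ||
        any(lengths(planted_patterns) != 2L)) {
      abort("Planted patterns must be pairs of pathway indices <= n_pathways.",
            class = "combipath_error")
    }
    if (2L * n_effective_pairs > n_drugs) {
      abort(sprintf("Need >= %d drugs for %d disjoint effective pairs.",
                    2L * n_effective_pairs, n_effective_pairs),
            class = "combipath_error")
    }
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a complete synthetic study collection
#'
#' Produces everything the pipeline consumes, with recorded ground truth:
#'
#' * pathway gene sets (disjoint blocks of genes when they fit, random draws
#'   otherwise);
#' * per-drug true affected-pathway sets: background pathways at
#'   `background_affect_rate`, plus, for the drugs enrolled in effective
#'   pairs, one side of a planted pattern each;
#' * per-drug treated/control expression: lognormal baseline per gene, with
#'   every gene of a drug's true affected pathways shifted by `effect_size`
#'   (log scale) in the treated arm;
#' * the effective-pair list — exactly the pairs built to co-realise a
#'   planted pattern.
#'
#' @param config A [synthetic_config()].
#' @return A list: `studies` (named list of [expression_study()]),
#'   `pathways` ([pathway_collection()]), `effective_pairs` (tibble),
#'   `truth` (list: `affected` — drug -> true pathway indices, `changed_genes`
#'   — drug -> truly shifted gene ids, `planted_patterns`, `pair_pattern` —
#'   planted pattern index per effective pair).
#' @export
make_study <- function(config = synthetic_config()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    pw_ids <- sprintf("PW%02d", seq_len(cfg$n_pathways))

    # pathway gene sets: disjoint consecutive blocks when the gene pool is
    # large enough, else independent random draws (overlap allowed)
    if (cfg$n_pathways * cfg$genes_per_pathway <= cfg$n_genes) {
      pool <- sample(gene_ids)
      gene_sets <- split(pool[seq_len(cfg$n_pathways * cfg$genes_per_pathway)],
                         rep(seq_len(cfg$n_pathways), each = cfg$genes_per_pathway))
      gene_sets <- unname(gene_sets)
    } else {
      gene_sets <- replicate(cfg$n_pathways,
                             sample(gene_ids, cfg$genes_per_pathway),
                             simplify = FALSE)
    }
    pathways <- pathway_collection(pw_ids, gene_sets)

    drug_ids <- sprintf("D%03d", seq_len(cfg$n_drugs))

    # background affected pathways for every drug
    affected <- lapply(drug_ids, function(d) {
      which(stats::runif(cfg$n_pathways) < cfg$background_affect_rate)
    })
    names(affected) <- drug_ids

    # enrol disjoint drug pairs as effective combinations; each pair is
    # assigned a planted pattern {i, j} and its two drugs are forced to
    # affect i and j respectively
    enrolled <- matrix(sample(drug_ids, 2L * cfg$n_effective_pairs),
                       ncol = 2L)
    pat_idx <- rep(seq_along(cfg$planted_patterns),
                   length.out = cfg$n_effective_pairs)
    for (r in seq_len(cfg$n_effective_pairs)) {
      pat <- cfg$planted_patterns[[pat_idx[r]]]
      side <- sample(2L)
      affected[[enrolled[r, 1]]] <- sort(union(affected[[enrolled[r, 1]]], pat[side[1]]))
      affected[[enrolled[r, 2]]] <- sort(union(affected[[enrolled[r, 2]]], pat[side[2]]))
    }
    effective_pairs <- canonical_pairs(
      tibble(drug_a = enrolled[, 1], drug_b = enrolled[, 2]))

    # expression: per-gene lognormal baseline shared across arms of a drug;
    # treated arm shifts the genes of the drug's affected pathways
    studies <- lapply(drug_ids, function(d) {
      base_log <- log(100) + rnorm(cfg$n_genes, sd = 0.5)
      shift <- rep(0, cfg$n_genes)
      changed <- unique(unlist(pathways$gene_sets[affected[[d]]], use.names = FALSE))
      shift[match(changed, gene_ids)] <- cfg$effect_size
      draw <- function(shifted) {
        noise <- matrix(rnorm(cfg$n_genes * cfg$replicates, sd = cfg$noise_sd),
                        cfg$n_genes, cfg$replicates)
        mu <- base_log + (if (shifted) shift else 0)
        exp(mu + noise)  # mu recycles down each replicate column
      }
      treated <- draw(TRUE)
      control <- draw(FALSE)
      expression_study(d, gene_ids, treated, control)
    })
    names(studies) <- drug_ids

    changed_genes <- lapply(drug_ids, function(d) {
      sort(unique(unlist(pathways$gene_sets[affected[[d]]], use.names = FALSE)))
    })
    names(changed_genes) <- drug_ids

    list(
      studies = studies,
      pathways = pathways,
      effective_pairs = effective_pairs,
      truth = list(affected = affected,
                   changed_genes = changed_genes,
                   planted_patterns = cfg$planted_patterns,
                   pair_pattern = pat_idx),
      config = cfg
    )
  })
}

#' Write a synthetic study collection to disk in the pipeline's formats
#'
#' Emits the same TSV/GMT/pairs layout the real pipeline reads (one
#' expression TSV per drug plus a manifest, a GMT file, and an
#' effective-pairs TSV), so synthetic and real runs are path-identical.
#'
#' @param sim Output of [make_study()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_dir <- file.path(dir, "expression")
  dir.create(expr_dir, showWarnings = FALSE)
  paths <- purrr::imap_chr(sim$studies, function(s, d) {
    p <- file.path(expr_dir, paste0(d, ".tsv"))
    write_expression_study(s, p)
    file.path("expression", paste0(d, ".tsv"))
  })
  readr::write_tsv(tibble(drug_id = names(sim$studies), path = unname(paths)),
                   file.path(dir, "manifest.tsv"))
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  write_pairs(sim$effective_pairs, file.path(dir, "effective_pairs.tsv"))
  invisible(dir)
}
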