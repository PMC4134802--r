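#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. Either point `manifest`, `gmt`
#' and `pairs` at real inputs, or set `synthetic = TRUE` to generate a
#' planted study collection first (see [synthetic_config()]).
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param manifest,gmt,pairs Input paths (ignored when `synthetic = TRUE`;
#'   filled in by [stage_simulate()]).
#' @param synthetic Generate inputs with [make_study()] first.
#' @param synthetic_args List of overrides for [synthetic_config()].
#' @param alpha Significance level for the fingerprinting stage's
#'   [differential_genes()] calls. The pipeline default (0.001) is stricter
#'   than the per-gene default: with existential pathway mapping, a raw
#'   alpha of 0.05 would flag a 25-gene pathway as affected with probability
#'   `1 - 0.95^25 ~ 0.72` from false-positive gene calls alone, saturating
#'   every fingerprint, whereas a truly affected pathway (all member genes
#'   shifted) is still detected essentially always at 0.001.
#' @param min_replicates Replicate filter for [filter_studies()].
#' @param representation `"frequent_pattern"` (default) or `"linear_addition"`.
#' @param n_random,pseudocount Passed to [frequency_scores()].
#' @param n_features Number of selected features; `NULL` applies the
#'   one-quarter rule [default_feature_count()].
#' @param kernel Kernel kind for the SVM stage.
#' @param cost,gamma Fixed SVM hyperparameters; a `NULL` `cost` triggers
#'   [grid_search()]; a `NULL` `gamma` defaults to 1/n_features.
#' @param grid_bounds Length-2 bounds for both grid axes (default
#'   `c(0.03125, 32)`).
#' @param folds CV folds (default 10).
#' @param nu One-class SVM outlier bound.
#' @param smoothing Naive Bayes pseudocount.
#' @param repeats Repeats for [repeated_split_eval()].
#' @param seed Master seed; stage seeds derive from it deterministically.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            manifest = NULL, gmt = NULL, pairs = NULL,
                            synthetic = FALSE, synthetic_args = list(),
                            alpha = 0.001, min_replicates = 3L,
                            representation = "frequent_pattern",
                            n_random = NULL, pseudocount = 1,
                            n_features = NULL,
                            kernel = "gaussian", cost = 1, gamma = NULL,
                            grid_bounds = c(0.03125, 32),
                            folds = 10L, nu = 0.1, smoothing = 1,
                            repeats = 10L, seed = 1L) {
  cfg <- list(out_dir = out_dir, manifest = manifest, gmt = gmt, pairs = pairs,
              synthetic = synthetic, synthetic_args = synthetic_args,
              alpha = alpha, min_replicates = min_replicates,
              representation = representation,
              n_random = n_random, pseudocount = pseudocount,
              n_features = n_features,
              kernel = kernel, cost = cost, gamma = gamma, grid_bounds = grid_bounds,
              folds = as.integer(folds), nu = nu, smoothing = smoothing,
              repeats = as.integer(repeats), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "combipath_config_error")
  }
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

validate_config <- function(config) {
  if (!config$synthetic) {
    for (key in c("manifest", "gmt", "pairs")) {
      p <- config[[key]]
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("Config error: `%s` path missing or does not exist (%s).",
                      key, p %||% "NULL"),
              class = "combipath_config_error")
      }
    }
  }
  if (!config$representation %in% c("frequent_pattern", "linear_addition")) {
    abort("Config error: unknown representation.", class = "combipath_config_error")
  }
  invisible(config)
}

log_line <- function(config, ...) {
  msg <- sprintf(...)
  message("[combipath] ", msg)
  cat(format(Sys.time(), "%H:%M:%S "), msg, "\n",
      file = file.path(config$out_dir, "run.log"), append = TRUE, sep = "")
}

#' Pipeline stages
#'
#' Each stage reads its inputs from disk and writes its outputs under the
#' config's `out_dir`, so the stages compose to exactly what [run_pipeline()]
#' produces and can be driven individually from the command line.
#'
#' * `stage_simulate()` — generate synthetic inputs (only when
#'   `synthetic = TRUE`); returns the config with input paths filled in.
#' * `stage_signatures()` — load studies, apply the replicate filter, call
#'   significant genes, map to pathway-affect vectors
#'   (`pathway_vectors.tsv`).
#' * `stage_patterns()` — score pathway-pair patterns against the
#'   random-pairing background (`patterns.tsv`).
#' * `stage_dataset()` — generate negatives, select features, build the
#'   feature matrix (`dataset.tsv`).
#' * `stage_evaluate()` — k-fold CV for the SVM (fixed parameters or grid
#'   search) and naive Bayes, plus the repeated independent split
#'   (`cv_metrics.tsv`, `independent_test.tsv`).
#'
#' @param config A [pipeline_config()].
#' @return Each stage invisibly returns its main in-memory product; see
#'   Details.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(config) {
  if (!config$synthetic) return(invisible(config))
  sim <- make_study(do.call(synthetic_config,
                            utils::modifyList(list(seed = config$seed),
                                              config$synthetic_args)))
  in_dir <- file.path(config$out_dir, "inputs")
  write_synthetic_inputs(sim, in_dir)
  config$manifest <- file.path(in_dir, "manifest.tsv")
  config$gmt <- file.path(in_dir, "pathways.gmt")
  config$pairs <- file.path(in_dir, "effective_pairs.tsv")
  log_line(config, "simulated %d drugs / %d pathways / %d effective pairs",
           length(sim$studies), length(sim$pathways), nrow(sim$effective_pairs))
  invisible(config)
}

write_vectors <- function(vectors, path) {
  wide <- purrr::imap_dfr(vectors, function(v, d) {
    dplyr::bind_cols(tibble(drug_id = d), as_tibble(as.list(v$bits)))
  })
  readr::write_tsv(wide, path)
  invisible(path)
}

read_vectors <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    drug_id = readr::col_character(), .default = readr::col_integer()))
  vecs <- lapply(seq_len(nrow(wide)), function(r) {
    bits <- unlist(wide[r, -1])
    structure(list(drug_id = wide$drug_id[r], bits = bits),
              class = "pathway_vector")
  })
  setNames(vecs, wide$drug_id)
}

#' @rdname pipeline-stages
#' @export
stage_signatures <- function(config) {
  validate_config(config)
  studies <- read_manifest(config$manifest)
  studies <- filter_studies(studies, config$min_replicates)
  if (length(studies) == 0L) {
    abort("No study passes the replicate filter.", class = "combipath_error")
  }
  pathways <- read_gmt(config$gmt)
  vectors <- pathway_fingerprints(studies, pathways, alpha = config$alpha)
  write_vectors(vectors, file.path(config$out_dir, "pathway_vectors.tsv"))
  log_line(config, "signatures: %d studies retained, %d pathways",
           length(studies), length(pathways))
  invisible(vectors)
}

#' @rdname pipeline-stages
#' @export
stage_patterns <- function(config) {
  vectors <- read_vectors(file.path(config$out_dir, "pathway_vectors.tsv"))
  positives <- read_pairs(config$pairs)
  positives <- positives[positives$drug_a %in% names(vectors) &
                           positives$drug_b %in% names(vectors), ]
  tbl <- frequency_scores(
    positives, vectors,
    n_random = config$n_random %||% (10L * nrow(positives)),
    pseudocount = config$pseudocount,
    seed = config$seed + 1L)
  write_pattern_table(tbl, file.path(config$out_dir, "patterns.tsv"))
  log_line(config, "patterns: %d scored, top score %.3f", nrow(tbl), max(tbl$score))
  invisible(tbl)
}

#' @rdname pipeline-stages
#' @export
stage_dataset <- function(config) {
  positives <- read_pairs(config$pairs)
  vectors <- read_vectors(file.path(config$out_dir, "pathway_vectors.tsv"))
  positives <- positives[positives$drug_a %in% names(vectors) &
                           positives$drug_b %in% names(vectors), ]
  negatives <- generate_negative_pairs(positives, seed = config$seed + 2L)
  pairs <- dplyr::bind_rows(
    dplyr::mutate(positives, label = "effective"),
    dplyr::mutate(negatives, label = "noneffective"))
  k <- config$n_features %||% default_feature_count(nrow(pairs))

  if (config$representation == "frequent_pattern") {
    tbl <- read_pattern_table(file.path(config$out_dir, "patterns.tsv"))
    sel <- select_frequent_patterns(tbl, min(k, nrow(tbl)))
    ds <- build_dataset(pairs, "frequent_pattern",
                        vectors = vectors, patterns = sel)
  } else {
    studies <- filter_studies(read_manifest(config$manifest),
                              config$min_replicates)
    ds <- build_dataset(pairs, "linear_addition", studies = studies)
    sel <- mrmr_select(ds, min(k, ncol(ds$X)))
    ds <- combination_dataset(ds$pairs, ds$X[, sel$index, drop = FALSE],
                              ds$y, feature_ids = sel$feature_id,
                              representation = "linear_addition")
  }
  write_selection(sel, file.path(config$out_dir, "selected_features.tsv"))
  write_dataset(ds, file.path(config$out_dir, "dataset.tsv"))
  log_line(config, "dataset: %d pairs x %d features (%s)",
           nrow(ds$X), ncol(ds$X), config$representation)
  invisible(ds)
}

#' Write / read a combination dataset as TSV
#'
#' The tidy layout (`drug_a`, `drug_b`, `label`, one column per feature) with
#' a `#representation` header comment.
#'
#' @param dataset A [combination_dataset()].
#' @param path File path.
#' @return `write_dataset()`: `path`, invisibly; `read_dataset()`: the
#'   restored [combination_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  writeLines(paste0("#representation\t", dataset$representation), path)
  readr::write_tsv(tidy.combination_dataset(dataset), path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  rep_line <- lines[startsWith(lines, "#representation")]
  representation <- if (length(rep_line) == 1L) {
    strsplit(rep_line, "\t", fixed = TRUE)[[1]][2]
  } else "custom"
  tbl <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         col_types = readr::cols(
                           drug_a = readr::col_character(),
                           drug_b = readr::col_character(),
                           label = readr::col_character(),
                           .default = readr::col_double()))
  feat <- setdiff(names(tbl), c("drug_a", "drug_b", "label"))
  combination_dataset(tbl[, c("drug_a", "drug_b")],
                      as.matrix(tbl[, feat, drop = FALSE]),
                      tbl$label, feature_ids = feat,
                      representation = representation)
}

#' @rdname pipeline-stages
#' @export
stage_evaluate <- function(config) {
  ds <- read_dataset(file.path(config$out_dir, "dataset.tsv"))
  if (is.null(config$cost)) {
    gs <- grid_search(ds, kind = config$kernel,
                      c_bounds = config$grid_bounds,
                      g_bounds = config$grid_bounds,
                      folds = config$folds, seed = config$seed + 3L)
    svm_cfg <- gs$best
    readr::write_tsv(tidy(gs), file.path(config$out_dir, "grid_search.tsv"))
    log_line(config, "grid search: best c = %g, g = %g (CV acc %.3f)",
             svm_cfg$c, svm_cfg$g, gs$cv_accuracy)
  } else {
    svm_cfg <- kernel_config(config$kernel, c = config$cost,
                             g = config$gamma %||% 1 / ncol(ds$X))
  }

  svm_cv <- kfold_cv(svm_trainer(svm_cfg), ds, k = config$folds,
                     seed = config$seed + 4L)
  nb_cv <- kfold_cv(nb_trainer(config$smoothing), ds, k = config$folds,
                    seed = config$seed + 4L)
  cv_tbl <- dplyr::bind_rows(
    dplyr::mutate(svm_cv$pooled, model = paste0("svm_", config$kernel), .before = 1),
    dplyr::mutate(nb_cv$pooled, model = "naive_bayes", .before = 1))
  readr::write_tsv(cv_tbl, file.path(config$out_dir, "cv_metrics.tsv"))

  split_tbl <- repeated_split_eval(svm_trainer(svm_cfg), ds,
                                   repeats = config$repeats,
                                   seed = config$seed + 5L)
  write_metrics(split_tbl, file.path(config$out_dir, "independent_test.tsv"))

  nb_model <- nb_fit(ds, smoothing = config$smoothing)
  write_nb_model(nb_model, file.path(config$out_dir, "nb_model.txt"))

  log_line(config, "evaluate: SVM CV acc %.3f, NB CV acc %.3f, split avg acc %.3f",
           svm_cv$pooled$acc, nb_cv$pooled$acc,
           split_tbl$acc[split_tbl$run == "average"])
  invisible(list(svm_cv = svm_cv, nb_cv = nb_cv, split = split_tbl,
                 svm_config = svm_cfg))
}

#' Run the whole prediction pipeline
#'
#' Composes [stage_simulate()], [stage_signatures()], [stage_patterns()]
#' (frequent-pattern representation only), [stage_dataset()] and
#' [stage_evaluate()], then writes a run manifest (`run_manifest.json` when
#' jsonlite is available, YAML otherwise) recording the config, its hash and
#' the stage outputs. Re-running with an identical config reproduces
#' identical metric tables.
#'
#' @param config A [pipeline_config()].
#' @return The [stage_evaluate()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- stage_simulate(config)
  validate_config(config)
  stage_signatures(config)
  if (config$representation == "frequent_pattern") stage_patterns(config)
  stage_dataset(config)
  res <- stage_evaluate(config)

  manifest <- list(
    package = "combipath",
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config),
    seed = config$seed,
    outputs = list.files(config$out_dir, recursive = TRUE)
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  } else {
    yaml::write_yaml(manifest, file.path(config$out_dir, "run_manifest.yaml"))
  }
  invisible(res)
}
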