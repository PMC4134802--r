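#' Kernel configuration for SVM training
#'
#' The four kernel families compared by the pipeline, with the two libsvm
#' hyperparameters that matter: the cost factor `c` and the kernel
#' coefficient `g` (ignored by the linear kernel). `gaussian` is the RBF
#' kernel `exp(-g * ||x - x'||^2)`; `polynomial` is degree 3 with zero offset;
#' `tanh` is the sigmoid kernel `tanh(g * <x, x'> )`.
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"gaussian"`, `"tanh"`.
#' @param c Cost factor, > 0.
#' @param g Kernel coefficient, > 0 (unused for linear).
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(kind = c("linear", "polynomial", "gaussian", "tanh"),
                          c = 1, g = 1) {
  kind <- match.arg(kind)
  if (c <= 0 || g <= 0) {
    abort("`c` and `g` must be positive.", class = "combipath_error")
  }
  structure(list(kind = kind, c = c, g = g), class = "kernel_config")
}

as_e1071_kernel <- function(kind) {
  switch(kind,
         linear = "linear",
         polynomial = "polynomial",
         gaussian = "radial",
         tanh = "sigmoid",
         abort(sprintf("Unknown kernel kind '%s'.", kind),
               class = "combipath_error"))
}

#' Train a two-class SVM on a combination dataset
#'
#' Thin deterministic wrapper around the libsvm solver (via e1071) with the
#' pipeline's kernel conventions. Features are not rescaled: pattern features
#' are already 0/1 and linear-addition features are centred ratios.
#'
#' @param dataset A [combination_dataset()] containing both classes.
#' @param config A [kernel_config()].
#' @return An `svm_fit`; use [predict()] with a feature matrix to get labels.
#' @export
train_svm <- function(dataset, config = kernel_config("gaussian")) {
  if (nlevels(droplevels(dataset$y)) < 2L) {
    abort("Both classes must be present to train a two-class SVM.",
          class = "combipath_error")
  }
  if (!all(is.finite(dataset$X))) {
    abort("Features must be finite.", class = "combipath_error")
  }
  fit <- e1071::svm(
    x = dataset$X, y = dataset$y,
    type = "C-classification",
    kernel = as_e1071_kernel(config$kind),
    cost = config$c, gamma = config$g,
    degree = 3, coef0 = 0,
    scale = FALSE
  )
  structure(list(fit = fit, config = config, feature_ids = dataset$feature_ids),
            class = "svm_fit")
}

#' @export
predict.svm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  factor(as.character(predict(object$fit, newdata)),
         levels = c("effective", "noneffective"))
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("<svm_fit> %s kernel, c = %g, g = %g, %d support vectors\n",
              x$config$kind, x$config$c, x$config$g, x$fit$tot.nSV))
  invisible(x)
}

#' Grid search over SVM cost and kernel coefficient
#'
#' Evaluates k-fold cross-validation accuracy at every point of a logarithmic
#' (powers-of-two) grid over `c` and `g` within the given bounds (default
#' 2^-5 ... 2^5, i.e. 0.03125 to 32) and returns the best configuration. Ties
#' break to the smaller `c`, then the smaller `g`, so the result is unique;
#' the fold assignment is seeded, so the whole search is reproducible. For the
#' linear kernel the `g` axis collapses to a single point.
#'
#' @param dataset A [combination_dataset()].
#' @param kind Kernel kind, see [kernel_config()].
#' @param c_bounds,g_bounds Length-2 positive bounds for the two axes.
#' @param log2_step Spacing of the grid in log2 units (default 1).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @return A `grid_search` list: `best` ([kernel_config()]), `cv_accuracy`,
#'   and `grid`, a tibble of every evaluated point.
#' @export
grid_search <- function(dataset, kind = "gaussian",
                        c_bounds = c(2^-5, 2^5), g_bounds = c(2^-5, 2^5),
                        log2_step = 1, folds = 10, seed = 1L) {
  if (any(c(c_bounds, g_bounds) <= 0)) {
    abort("Grid bounds must be positive.", class = "combipath_error")
  }
  axis <- function(b) 2^seq(log2(b[1]), log2(b[2]), by = log2_step)
  c_vals <- axis(c_bounds)
  g_vals <- if (kind == "linear") 1 else axis(g_bounds)
  grid <- tidyr::expand_grid(c = c_vals, g = g_vals)
  if (nrow(grid) == 0L) {
    abort("Empty parameter grid.", class = "combipath_error")
  }
  acc <- purrr::pmap_dbl(grid, function(c, g) {
    cv <- kfold_cv(svm_trainer(kernel_config(kind, c = c, g = g)),
                   dataset, k = folds, seed = seed)
    cv$pooled$acc
  })
  grid <- dplyr::mutate(grid, accuracy = acc)
  ord <- order(-grid$accuracy, grid$c, grid$g)
  best <- grid[ord[1], ]
  structure(
    list(best = kernel_config(kind, c = best$c, g = best$g),
         cv_accuracy = best$accuracy,
         kind = kind, folds = folds, seed = seed,
         grid = grid),
    class = "grid_search"
  )
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> %s kernel over %d points: best c = %g, g = %g (CV accuracy %.3f)\n",
              x$kind, nrow(x$grid), x$best$c, x$best$g, x$cv_accuracy))
  invisible(x)
}

#' @rdname grid_search
#' @param x A `grid_search`.
#' @param ... Unused.
#' @return `tidy()`: the evaluated grid as a tibble; `glance()`: a one-row
#'   tibble with the winning configuration.
#' @export
tidy.grid_search <- function(x, ...) as_tibble(x$grid)

#' @rdname grid_search
#' @export
glance.grid_search <- function(x, ...) {
  tibble(kind = x$kind, c = x$best$c, g = x$best$g,
         cv_accuracy = x$cv_accuracy, n_grid = nrow(x$grid))
}

#' Train a one-class SVM novelty detector on effective pairs only
#'
#' Learns the support of the effective-combination feature distribution from
#' positives alone; new pairs are labelled inliers (effective-like) or
#' outliers. `nu` upper-bounds the fraction of training points treated as
#' outliers.
#'
#' @param X Feature matrix of positive (effective) pairs, >= 2 rows.
#' @param kind Kernel kind (default `"gaussian"`).
#' @param g Kernel coefficient (default `1 / ncol(X)`).
#' @param nu Outlier-fraction bound in (0, 1], default 0.1.
#' @return An `ocsvm_fit`; [predict()] returns a logical inlier flag per row.
#' @export
train_one_class_svm <- function(X, kind = "gaussian", g = 1 / ncol(X), nu = 0.1) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    abort("Need >= 2 positive samples.", class = "combipath_error")
  }
  if (!(nu > 0 && nu <= 1)) {
    abort("`nu` must be in (0, 1].", class = "combipath_error")
  }
  # the libsvm solver degenerates at exactly nu = 1 (every point an outlier);
  # map the boundary to the nearest interior value
  nu <- min(nu, 1 - 1e-6)
  fit <- e1071::svm(
    x = X, y = NULL,
    type = "one-classification",
    kernel = as_e1071_kernel(kind),
    gamma = g, nu = nu,
    degree = 3, coef0 = 0,
    scale = FALSE
  )
  structure(list(fit = fit, kind = kind, g = g, nu = nu, p = ncol(X)),
            class = "ocsvm_fit")
}

#' @export
predict.ocsvm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.logical(predict(object$fit, newdata))
}

#' @export
print.ocsvm_fit <- function(x, ...) {
  cat(sprintf("<ocsvm_fit> %s kernel, g = %g, nu = %g\n", x$kind, x$g, x$nu))
  invisible(x)
}
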