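nb_toy <- function() {
  # 4 samples, 2 per class; binary feature positive twice in the effective
  # class and never in the noneffective class
  drugs <- sprintf("D%d", 1:8)
  combination_dataset(
    tibble::tibble(drug_a = drugs[1:4], drug_b = drugs[5:8]),
    matrix(c(1, 1, 0, 0), 4, 1),
    c("effective", "effective", "noneffective", "noneffective"),
    "f1")
}

test_that("Laplace smoothing and priors follow the closed forms", {
  m <- nb_fit(nb_toy(), smoothing = 1)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  expect_equal(m$bernoulli["f1", "effective"], (2 + 1) / (2 + 2))
  expect_equal(m$bernoulli["f1", "noneffective"], (0 + 1) / (2 + 2))
  expect_equal(sum(m$priors), 1, tolerance = 1e-12)
})

test_that("posteriors equal the hand-multiplied Bayes product", {
  m <- nb_fit(nb_toy(), smoothing = 1)
  pr <- nb_predict(m, matrix(1, 1, 1))
  # prior 0.5 each; likelihoods 0.75 vs 0.25 -> posterior 3:1
  expect_equal(unname(pr$posterior[1, ]), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(as.character(pr$labels), "effective")
  pr0 <- nb_predict(m, matrix(0, 1, 1))
  expect_equal(unname(pr0$posterior[1, ]), c(0.25, 0.75), tolerance = 1e-12)

  # symmetric model: uniform posterior, tie broken to the first class
  sym <- combination_dataset(
    tibble::tibble(drug_a = c("a", "b"), drug_b = c("c", "d")),
    matrix(c(1, 1), 2, 1), c("effective", "noneffective"), "f1")
  ms <- nb_fit(sym, smoothing = 1)
  ps <- nb_predict(ms, matrix(1, 1, 1))
  expect_equal(unname(ps$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(as.character(ps$labels), "effective")
})

test_that("posterior is monotone in a feature's likelihood ratio", {
  # sweep the effective-class Bernoulli rate upward while holding everything
  # else fixed: the posterior for effective at x = 1 must never decrease
  m <- nb_fit(nb_toy(), smoothing = 1)
  ps <- seq(0.05, 0.95, by = 0.05)
  post <- vapply(ps, function(p) {
    m$bernoulli["f1", "effective"] <- p
    nb_predict(m, matrix(1, 1, 1))$posterior[1, "effective"]
  }, numeric(1))
  expect_true(all(diff(post) > 0))
  # same sweep at x = 0 flips the ratio, so the posterior must decrease
  post0 <- vapply(ps, function(p) {
    m$bernoulli["f1", "effective"] <- p
    nb_predict(m, matrix(0, 1, 1))$posterior[1, "effective"]
  }, numeric(1))
  expect_true(all(diff(post0) < 0))
})

assign_part_half <- function(p) if (p == 1) 1:10 else 11:20

test_that("partition-aggregate training equals the sequential fit", {
  withr::with_seed(16, {
    n <- 20
    X <- cbind(rbinom(n, 1, 0.4), rnorm(n, 5, 2), rbinom(n, 1, 0.6), rnorm(n))
    y <- rep(c("effective", "noneffective"), each = 10)
    drugs <- sprintf("D%02d", 1:40)
    ds <- combination_dataset(tibble::tibble(drug_a = drugs[1:20],
                                             drug_b = drugs[21:40]),
                              X, y, paste0("f", 1:4))
  })
  full <- nb_fit(ds, smoothing = 1)
  for (parts in list(1, 2, 5)) {
    assign_part <- withr::with_seed(parts, sample(rep(seq_len(parts), length.out = 20)))
    stats <- lapply(seq_len(parts), function(p)
      nb_map(subset_dataset(ds, assign_part == p), classes = levels(ds$y)))
    red <- nb_reduce(stats, smoothing = 1)
    expect_identical(red$class_counts, full$class_counts)
    expect_equal(red$priors, full$priors, tolerance = 1e-12)
    expect_equal(red$bernoulli, full$bernoulli, tolerance = 1e-12)
    expect_equal(red$mean, full$mean, tolerance = 1e-12)
    expect_equal(red$var, full$var, tolerance = 1e-12)
    expect_identical(red$feature_types, full$feature_types)
  }
  # an empty partition is an additive identity
  empty <- nb_map(subset_dataset(ds, integer(0)), classes = levels(ds$y))
  two <- lapply(1:2, function(p) nb_map(subset_dataset(ds, assign_part_half(p)),
                                        classes = levels(ds$y)))
  expect_equal(nb_reduce(c(two, list(empty)), 1)$bernoulli,
               nb_reduce(two, 1)$bernoulli, tolerance = 1e-15)
})

test_that("posteriors sum to one and dimensions are checked", {
  ds <- fixture_dataset(n = 16, p = 3, seed = 18, binary = TRUE, separation = 1)
  m <- nb_fit(ds)
  pr <- nb_predict(m, ds$X)
  expect_equal(rowSums(pr$posterior), rep(1, 16), tolerance = 1e-12)
  expect_error(nb_predict(m, ds$X[, 1:2]), class = "combipath_error")
  solo <- subset_dataset(ds, which(ds$y == "effective"))
  expect_error(nb_fit(solo), class = "combipath_error")
})

test_that("naive Bayes models survive the plain-text round trip", {
  withr::with_seed(20, {
    n <- 12
    X <- cbind(rbinom(n, 1, 0.5), rnorm(n, 2, 1))
    drugs <- sprintf("D%02d", 1:24)
    ds <- combination_dataset(tibble::tibble(drug_a = drugs[1:12],
                                             drug_b = drugs[13:24]),
                              X, rep(c("effective", "noneffective"), 6),
                              c("pat", "ratio"))
  })
  m <- nb_fit(ds, smoothing = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_nb_model(m, path)
  m2 <- read_nb_model(path)
  expect_equal(m2$priors, m$priors)
  expect_equal(m2$bernoulli, m$bernoulli)
  expect_equal(m2$mean, m$mean)
  expect_equal(m2$var, m$var)
  expect_equal(m2$smoothing, m$smoothing)
  expect_equal(nb_predict(m2, ds$X)$posterior, nb_predict(m, ds$X)$posterior,
               tolerance = 1e-12)
})
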