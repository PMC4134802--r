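test_that("expression studies round-trip through the TSV layout", {
  withr::with_seed(11, {
    tr <- matrix(rlnorm(12), 3, 4)
    ct <- matrix(rlnorm(9), 3, 3)
  })
  s <- fixture_study("dX", tr, ct)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_study(s, path)
  s2 <- read_expression_study(path, "dX")
  expect_equal(s2$gene_ids, s$gene_ids)
  expect_equal(unname(s2$treated), unname(tr), tolerance = 1e-12)
  expect_equal(unname(s2$control), unname(ct), tolerance = 1e-12)

  # 3-gene, 2+2 fixture reads back with the right shapes
  expect_identical(dim(fixture_study("d", matrix(1:6 + 0.5, 3, 2),
                                     matrix(1:6 + 0.1, 3, 2))$treated),
                   c(3L, 2L))
})

test_that("invalid expression inputs are rejected", {
  expect_error(fixture_study("d", matrix(c(1, 0, 2, 3), 2, 2),
                             matrix(1:4 + 0.1, 2, 2)),
               class = "combipath_error")  # zero value
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttreated_1\tweird_2", "G1\t1.0\t2.0"), path)
  expect_error(read_expression_study(path, "d"), class = "combipath_format_error")
  writeLines(c("gene_id\ttreated_1\tcontrol_1", "G1\t1.0\tabc"), path)
  suppressWarnings(
    expect_error(read_expression_study(path, "d"), class = "combipath_parse_error"))
})

test_that("replicate filter retains and excludes by both arms", {
  s33 <- fixture_study("a", matrix(1:9 + 0.1, 3, 3), matrix(1:9 + 0.2, 3, 3))
  s25 <- fixture_study("b", matrix(1:6 + 0.1, 3, 2), matrix(1:15 + 0.2, 3, 5))
  expect_true(filter_by_replicates(s33, 3)$retained)
  expect_false(filter_by_replicates(s25, 3)$retained)
  expect_true(filter_by_replicates(s25, 1)$retained)
  expect_named(filter_studies(list(a = s33, b = s25), 3), "a")
})

test_that("differential_genes matches the pooled t-test oracle", {
  # hand-constructed gene: huge shift, control variance only
  s <- fixture_study("d", matrix(c(10, 10, 10), 1, 3), matrix(c(1, 1.1, 0.9), 1, 3))
  sig <- differential_genes(s, alpha = 0.05)
  tt <- stats::t.test(c(10, 10, 10), c(1, 1.1, 0.9), var.equal = TRUE)
  expect_equal(sig$stats$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(sig$stats$p_value, tt$p.value, tolerance = 1e-10)
  expect_identical(sig$significant_genes, "G1")
  expect_equal(sig$stats$statistic, oracle_pooled_t(c(10, 10, 10), c(1, 1.1, 0.9)),
               tolerance = 1e-10)

  # per-gene agreement with both stats::t.test and the textbook loop
  withr::with_seed(5, {
    tr <- matrix(rlnorm(40, log(50), 0.4), 10, 4)
    ct <- matrix(rlnorm(30, log(50), 0.4), 10, 3)
  })
  st <- fixture_study("d2", tr, ct)
  res <- differential_genes(st, alpha = 0.5)$stats
  for (i in 1:10) {
    expect_equal(res$statistic[i], oracle_pooled_t(tr[i, ], ct[i, ]),
                 tolerance = 1e-10)
    expect_equal(res$p_value[i],
                 stats::t.test(tr[i, ], ct[i, ], var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # Welch variant agrees with stats::t.test(var.equal = FALSE)
  resw <- differential_genes(st, alpha = 0.5, var_equal = FALSE)$stats
  expect_equal(resw$p_value[1],
               stats::t.test(tr[1, ], ct[1, ])$p.value, tolerance = 1e-10)
})

test_that("differential_genes edge behaviour: zero effect, flat genes, alpha = 1", {
  tr <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3)
  s <- fixture_study("d", tr, tr)  # identical arms
  expect_length(differential_genes(s, 0.05)$significant_genes, 0)

  # flat gene in both arms gets p = 1, not NaN
  flat <- fixture_study("d", matrix(5, 1, 3), matrix(5, 1, 3))
  res <- differential_genes(flat, 0.05)$stats
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  # alpha = 1 picks up every gene with a finite statistic
  withr::with_seed(3, {
    st <- fixture_study("d", matrix(rlnorm(9), 3, 3), matrix(rlnorm(9), 3, 3))
  })
  expect_length(differential_genes(st, 1)$significant_genes, 3)

  expect_error(differential_genes(fixture_study("d", matrix(1.5, 1, 1),
                                                matrix(c(1, 2), 1, 2)), 0.05),
               class = "combipath_precondition_error")
})

test_that("significance calls are replicate-order invariant and monotone in alpha", {
  withr::with_seed(7, {
    tr <- matrix(rlnorm(20, log(30), 0.5), 5, 4)
    ct <- matrix(rlnorm(20, log(40), 0.5), 5, 4)
  })
  s <- fixture_study("d", tr, ct)
  perm <- fixture_study("d", tr[, c(3, 1, 4, 2)], ct[, c(2, 4, 1, 3)])
  expect_equal(differential_genes(s, 0.2)$significant_genes,
               differential_genes(perm, 0.2)$significant_genes)
  for (pair in list(c(0.01, 0.05), c(0.05, 0.2), c(0.2, 1))) {
    expect_true(all(differential_genes(s, pair[1])$significant_genes %in%
                      differential_genes(s, pair[2])$significant_genes))
  }
})
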