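test_that("linear-addition feature follows the centred-ratio arithmetic", {
  a <- constant_study("a", tr = 5, ct = 10)    # P/C - 1 = 1
  b <- constant_study("b", tr = 3, ct = 6)     # P/C - 1 = 1
  expect_equal(unname(linear_addition_feature(a, b)), 2)
  # no-effect null
  n1 <- constant_study("a", tr = 7, ct = 7)
  n2 <- constant_study("b", tr = 4, ct = 4)
  expect_equal(unname(linear_addition_feature(n1, n2)), 0)
  # symmetry under drug swap
  expect_equal(linear_addition_feature(a, b), linear_addition_feature(b, a))
  # flipped orientation gives C/P - 1
  expect_equal(unname(linear_addition_feature(a, b, orientation = "treated_over_control")),
               (5 / 10 - 1) + (3 / 6 - 1))
  # restricted to shared genes, sorted
  s1 <- fixture_study("a", matrix(c(2, 3), 2, 1), matrix(c(4, 6), 2, 1),
                      genes = c("G2", "G1"))
  s2 <- fixture_study("b", matrix(5, 1, 1), matrix(10, 1, 1), genes = "G1")
  v <- linear_addition_feature(s1, s2)
  expect_named(v, "G1")
  expect_equal(unname(v), (6 / 3 - 1) + (10 / 5 - 1))
  s3 <- fixture_study("c", matrix(1.5, 1, 1), matrix(2.5, 1, 1), genes = "ZZ")
  expect_error(linear_addition_feature(s1, s3), class = "combipath_error")
})

test_that("extract_patterns enumerates exactly the cross products", {
  pat <- function(m) apply(m, 1, paste, collapse = ":")
  expect_equal(pat(extract_patterns(c(1, 0), c(0, 1))), "1:2")
  expect_equal(pat(extract_patterns(c(1, 1), c(1, 1))), c("1:1", "1:2", "2:2"))
  expect_equal(nrow(extract_patterns(c(0, 0), c(1, 1))), 0)
  expect_error(extract_patterns(c(1, 0), c(1, 0, 1)), class = "combipath_error")

  # brute-force enumeration oracle on random vectors, plus symmetry
  withr::with_seed(9, {
    for (rep in 1:25) {
      a <- rbinom(6, 1, 0.4); b <- rbinom(6, 1, 0.4)
      got <- extract_patterns(a, b)
      want <- character(0)
      for (i in which(a == 1)) for (j in which(b == 1)) {
        want <- c(want, paste(min(i, j), max(i, j), sep = ":"))
      }
      expect_setequal(pat(got), unique(want))
      expect_equal(extract_patterns(a, b), extract_patterns(b, a))
    }
  })
})

test_that("frequency scores implement S = N(EC) / (N(RC) + pseudocount)", {
  # all drugs share one affected pathway -> the diagonal pattern is in every
  # pair, effective or random, so its scaled background count equals the
  # effective count exactly
  vecs <- lapply(c("A", "B", "C", "D"), function(d) {
    structure(list(drug_id = d, bits = setNames(c(1L, 0L), c("P1", "P2"))),
              class = "pathway_vector")
  })
  names(vecs) <- c("A", "B", "C", "D")
  eff <- tibble::tibble(drug_a = c("A", "C"), drug_b = c("B", "D"))
  tbl0 <- frequency_scores(eff, vecs, n_random = 50, pseudocount = 0, seed = 4)
  expect_equal(tbl0$pattern, "1:1")
  expect_equal(tbl0$n_ec, 2)
  expect_equal(tbl0$n_rc, 2)  # every random pair also realises it, scaled to 2
  expect_equal(tbl0$score, 1)
  # pseudocount shifts the denominator
  tbl1 <- frequency_scores(eff, vecs, n_random = 50, pseudocount = 1, seed = 4)
  expect_equal(tbl1$score, 2 / 3)
  # the score column always equals the ratio recomputed from the count columns
  expect_equal(tbl1$score, tbl1$n_ec / (tbl1$n_rc + 1))

  expect_error(frequency_scores(eff[0, ], vecs), class = "combipath_error")
  expect_identical(frequency_scores(eff, vecs, seed = 11),
                   frequency_scores(eff, vecs, seed = 11))
})

test_that("frequency scores are equivariant under pathway relabelling", {
  withr::with_seed(31, {
    drugs <- sprintf("D%d", 1:8)
    bits <- lapply(drugs, function(d) rbinom(5, 1, 0.5))
    mkvec <- function(b, d, nm) structure(
      list(drug_id = d, bits = setNames(as.integer(b), nm)),
      class = "pathway_vector")
    nm <- paste0("P", 1:5)
    vecs <- setNames(purrr::map2(bits, drugs, mkvec, nm = nm), drugs)
    eff <- tibble::tibble(drug_a = c("D1", "D3", "D5"), drug_b = c("D2", "D4", "D6"))
    perm <- sample(5)
    vecs_p <- setNames(purrr::map2(lapply(bits, function(b) b[perm]), drugs,
                                   mkvec, nm = nm[perm]), drugs)
    t1 <- frequency_scores(eff, vecs, n_random = 40, seed = 2)
    t2 <- frequency_scores(eff, vecs_p, n_random = 40, seed = 2)
    # map t1's indices through the permutation and compare score multisets
    inv <- order(perm)
    relabel <- function(i, j) paste(pmin(inv[i], inv[j]), pmax(inv[i], inv[j]), sep = ":")
    key1 <- relabel(t1$i, t1$j)
    expect_setequal(key1, t2$pattern)
    expect_equal(t1$score[match(t2$pattern, key1)], t2$score)
  })
})

test_that("build_dataset produces aligned indicator and ratio matrices", {
  vecs <- list(
    A = structure(list(drug_id = "A", bits = c(P1 = 1L, P2 = 0L, P3 = 1L)),
                  class = "pathway_vector"),
    B = structure(list(drug_id = "B", bits = c(P1 = 0L, P2 = 1L, P3 = 0L)),
                  class = "pathway_vector"),
    C = structure(list(drug_id = "C", bits = c(P1 = 0L, P2 = 0L, P3 = 1L)),
                  class = "pathway_vector"))
  pairs <- tibble::tibble(drug_a = c("A", "A"), drug_b = c("B", "C"),
                          label = c("effective", "noneffective"))
  patterns <- cbind(i = c(1L, 1L, 3L), j = c(2L, 3L, 3L))
  ds <- build_dataset(pairs, "frequent_pattern", vectors = vecs, patterns = patterns)
  # pair A+B realises {1,2},{2,3} of which selected: {1,2} yes, {1,3} no, {3,3} no
  expect_equal(unname(ds$X[1, ]), c(1L, 0L, 0L))
  # pair A+C realises {1,3},{3,3}
  expect_equal(unname(ds$X[2, ]), c(0L, 1L, 1L))
  expect_equal(levels(ds$y), c("effective", "noneffective"))

  a <- constant_study("A", tr = 5, ct = 10)
  b <- constant_study("B", tr = 3, ct = 6)
  dl <- build_dataset(tibble::tibble(drug_a = "A", drug_b = "B", label = "effective"),
                      "linear_addition", studies = list(A = a, B = b))
  expect_equal(unname(dl$X[1, 1]), 2)

  expect_error(build_dataset(pairs[0, ], "frequent_pattern",
                             vectors = vecs, patterns = patterns),
               class = "combipath_error")
  expect_error(build_dataset(pairs, "nonsense"), "arg")
})

test_that("dataset TSV round-trips through write_dataset/read_dataset", {
  ds <- fixture_dataset(n = 10, p = 3, seed = 2, binary = FALSE, separation = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  expect_equal(ds2$y, ds$y)
  expect_equal(unname(ds2$X), unname(ds$X), tolerance = 1e-12)
  expect_equal(ds2$representation, ds$representation)
})

test_that("negative pairs are disjoint, distinct, sized and seeded", {
  pos <- canonical_pairs(tibble::tibble(drug_a = c("a", "b", "c"),
                                        drug_b = c("b", "c", "d")))
  neg <- generate_negative_pairs(pos, seed = 3)
  expect_equal(nrow(neg), 3)
  expect_length(intersect(paste(neg$drug_a, neg$drug_b),
                          paste(pos$drug_a, pos$drug_b)), 0)
  expect_identical(neg, generate_negative_pairs(pos, seed = 3))
  # universe of 4 drugs has 6 pairs, 3 are positive -> at most 3 negatives
  expect_error(generate_negative_pairs(pos, n = 4, seed = 1),
               class = "combipath_error")
  # positives exhausting all pairs of 3 drugs
  full <- canonical_pairs(tibble::tibble(drug_a = c("a", "a", "b"),
                                         drug_b = c("b", "c", "c")))
  expect_error(generate_negative_pairs(full, n = 1, seed = 1),
               class = "combipath_error")
})
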