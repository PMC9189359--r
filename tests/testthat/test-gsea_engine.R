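test_that("indicator marks membership and carries N_H and weighted N_R", {
  ranked <- rank_genes(delta_vector(c("A", "B", "C"), c(1, 3, 2)))  # B,C,A
  ind <- indicator(ranked, c("A", "C"))
  expect_identical(ind$r, c(0L, 1L, 1L))
  expect_equal(ind$N_H, 2L)
  expect_equal(ind$N_R, 2 + 1)
  expect_equal(indicator(ranked, "ZZZ")$N_R, 0)
  expect_equal(indicator(ranked, c("A", "B", "C"))$N_H, 3L)
  half <- indicator(ranked, c("A", "C"), p = 0.5)
  expect_equal(half$N_R, sqrt(2) + 1)
})

test_that("the running-sum recurrence reproduces the hand-iterated curve", {
  curve <- es_curve(c(4, 3, 2, 1), c(1L, 0L, 0L, 1L), p = 1)
  expect_equal(curve, c(0.8, 0.3, -0.2, 0.0), tolerance = 1e-12)
  pk <- es_max(curve)
  expect_equal(pk$es_max, 0.8)
  expect_identical(pk$peak_index, 1L)
})

test_that("disjoint sets give the all-zero curve (N_R = 0 guard)", {
  expect_identical(es_curve(c(3, 2, 1), c(0L, 0L, 0L)), c(0, 0, 0))
  # zero deltas on every hit also force N_R = 0
  expect_identical(es_curve(c(1, 0, 0), c(0L, 1L, 1L)), c(0, 0, 0))
})

test_that("es_n vanishes for every input with N_R > 0", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(2:120, 1)
    delta <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    r <- integer(n)
    r[sample(n, sample(n - 1, 1))] <- 1L   # at least one miss: the identity
    p <- runif(1)                          # needs a defined miss step
    curve <- es_curve(delta, r, p)
    if (sum(r * abs(delta)^p) > 0) expect_lt(abs(curve[n]), 1e-12)
  }
})

test_that("the recurrence equals the classic two-term running sum", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(5:150, 1)
    delta <- sort(rnorm(n, sd = 3), decreasing = TRUE)
    r <- integer(n); r[sample(n, sample(n - 1, 1))] <- 1L
    p <- runif(1)
    expect_equal(es_curve(delta, r, p), oracle_es_curve(delta, r, p),
                 tolerance = 1e-10)
  }
  # all-hits edge case: no miss term is ever evaluated, curve ends at 1
  delta <- c(5, 1, 0.5)
  expect_equal(es_curve(delta, c(1L, 1L, 1L), p = 1),
               oracle_es_curve(delta, c(1L, 1L, 1L), p = 1), tolerance = 1e-12)
  expect_equal(es_curve(delta, c(1L, 1L, 1L), p = 1)[3], 1)
})

test_that("es_max agrees with fgsea's statistic on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(303)
  for (rep in 1:25) {
    n <- 80
    delta <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    hits <- sort(sample(n, 12))
    r <- integer(n); r[hits] <- 1L
    ours <- es_max(es_curve(delta, r, p = 1))$es_max
    ref <- fgsea::calcGseaStat(stats::setNames(delta, paste0("g", 1:n)),
                               selectedStats = hits, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("es_max takes the first index attaining the maximum magnitude", {
  expect_equal(es_max(c(-0.5, -0.9, -0.1, 0))$es_max, -0.9)
  expect_identical(es_max(c(-0.5, -0.9, -0.1, 0))$peak_index, 2L)
  expect_identical(es_max(c(0.4, -0.4, 0.4, 0))$peak_index, 1L)
  expect_identical(es_max(c(0, 0, 0))$peak_index, 1L)
  expect_equal(es_max(c(0, 0, 0))$es_max, 0)
})

test_that("the fast permutation kernel matches the recurrence maximum", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(3:100, 1)
    delta <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    N_H <- sample(n, 1)
    idx <- sample(n, N_H)
    r <- integer(n); r[idx] <- 1L
    w <- abs(delta)
    expect_equal(gsear:::.abs_es_max_at(w, idx, n, N_H, sum(w[idx])),
                 max(abs(es_curve(delta, r, p = 1))), tolerance = 1e-12)
  }
})

test_that("permutation nulls are seeded, sized and degenerate correctly", {
  set.seed(1)
  ranked <- random_ranked(60)
  null1 <- permutation_null(ranked, ranked$gene[c(3, 9, 20)], v = 100, seed = 5)
  null2 <- permutation_null(ranked, ranked$gene[c(3, 9, 20)], v = 100, seed = 5)
  expect_identical(null1, null2)
  expect_length(null1$values, 100L)
  expect_true(all(null1$values >= 0) && !is.unsorted(null1$values))
  # growing v extends the stream rather than reshuffling it
  null3 <- permutation_null(ranked, ranked$gene[c(3, 9, 20)], v = 150, seed = 5)
  expect_true(all(null1$values %in% null3$values))

  # permutation-invariant case: every gene is a member
  all_null <- permutation_null(ranked, ranked$gene, v = 20, seed = 2)
  obs <- max(abs(es_curve(ranked$delta, indicator(ranked, ranked$gene))))
  expect_equal(all_null$values, rep(obs, 20), tolerance = 1e-12)
})

test_that("empirical p is one minus the null ECDF", {
  null <- structure(list(values = c(0.1, 0.2, 0.3, 0.4), v = 4L, seed = 1L),
                    class = "null_dist")
  expect_equal(empirical_p(0.25, null), 0.5)
  expect_equal(empirical_p(0.4, null), 0)    # at or above every null value
  expect_equal(empirical_p(0.05, null), 1)   # below every null value
  expect_error(empirical_p(0.5, structure(list(values = numeric(0)),
                                          class = "null_dist")), "empty")
})

test_that("leading edges follow the piecewise definition in both modes", {
  ranked <- rank_genes(delta_vector(c("A", "B", "C", "D"), c(4, 3, 2, 1)))
  r <- c(1L, 0L, 0L, 1L)
  curve <- es_curve(ranked$delta, r, p = 1)
  pk <- es_max(curve)
  expect_identical(leading_edge(ranked, r, pk$es_max, pk$peak_index), "A")
  # printed strict form: j < i is empty when the peak is the first hit
  expect_identical(leading_edge(ranked, r, pk$es_max, pk$peak_index,
                                mode = "paper_strict"), character(0))
  # negative peak keeps hits at or after the peak in both modes
  expect_identical(leading_edge(ranked, c(0L, 1L, 0L, 1L), -0.5, 3L), "D")
  expect_identical(leading_edge(ranked, c(0L, 1L, 0L, 1L), -0.5, 3L,
                                mode = "paper_strict"), "D")
  expect_identical(leading_edge(ranked, r, 0, 1L), character(0))
})

test_that("run_gsea produces per-set results, is pure, and handles edge cases", {
  set.seed(9)
  ranked <- random_ranked(80)
  coll <- gene_set_collection(list(
    a = ranked$gene[c(1, 2, 3, 10, 15)],
    a_copy = ranked$gene[c(1, 2, 3, 10, 15)],
    disjoint = c("zz1", "zz2")))
  res <- run_gsea(ranked, coll, v = 200, seed = 11)
  expect_s3_class(res, "gsea_result")
  expect_equal(nrow(res), 3L)
  # identical sets get identical results (functional purity)
  expect_equal(res$es_max[1], res$es_max[2])
  expect_equal(res$p_value[1], res$p_value[2])
  expect_identical(res$leading_edge[[1]], res$leading_edge[[2]])
  # disjoint set: zero ES, empty leading edge, p = 1 by convention
  expect_equal(res$es_max[3], 0)
  expect_identical(res$leading_edge[[3]], character(0))
  expect_equal(res$p_value[3], 1)
  expect_equal(res$bh_fdr, stats::p.adjust(res$p_value, "BH"))

  res2 <- run_gsea(ranked, coll, v = 200, seed = 11)
  expect_identical(res, res2)
  expect_warning(empty <- run_gsea(ranked, gene_set_collection(
    stats::setNames(list(), character(0))), v = 10, seed = 1), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("results are invariant under permuting the ranked input's gene labels", {
  set.seed(13)
  ranked <- random_ranked(50)
  members <- ranked$gene[c(2, 5, 9, 33)]
  ind <- indicator(ranked, members)
  pk <- es_max(es_curve(ranked$delta, ind))
  # feeding the same (gene, delta) pairs in shuffled order must not matter:
  # rank_genes restores the canonical order first
  shuffle <- sample(nrow(ranked))
  ranked2 <- rank_genes(delta_vector(ranked$gene[shuffle],
                                     ranked$delta[shuffle]))
  pk2 <- es_max(es_curve(ranked2$delta, indicator(ranked2, members)))
  expect_equal(pk, pk2)
})

test_that("the leading-edge union pools significant sets in best-rank order", {
  ranked <- rank_genes(delta_vector(paste0("g", 1:6), c(6, 5, 4, 3, 2, 1)))
  res <- data.frame(set_id = c("s1", "s2", "s3"),
                    es_max = c(0.5, 0.4, 0.3),
                    peak_index = c(3L, 4L, 2L),
                    p_value = c(0.01, 0.02, 0.9), stringsAsFactors = FALSE)
  res$bh_fdr <- stats::p.adjust(res$p_value, "BH")
  res$n_hits <- c(2L, 2L, 1L)
  res$leading_edge <- list(c("g2", "g3"), c("g3", "g4"), "g1")
  attr(res, "ranked") <- ranked
  class(res) <- c("gsea_result", "data.frame")
  un <- union_leading_edges(res, alpha = 0.05)
  expect_identical(un$gene, c("g2", "g3", "g4"))
  expect_equal(un$delta, c(5, 4, 3))
  expect_identical(union_leading_edges(res, alpha = 0.001)$gene, character(0))
  expect_setequal(union_leading_edges(res, alpha = 1)$gene,
                  c("g1", "g2", "g3", "g4"))
})
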