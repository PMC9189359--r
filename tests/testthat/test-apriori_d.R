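test_that("support counts contiguous containment once per transaction", {
  tx <- wx_transactions()
  wx <- worked_example()
  # the eight reference supports reproduced by contiguous counting
  consistent <- wx$support[!wx$support$known_discrepancy, ]
  for (i in seq_len(nrow(consistent))) {
    chain <- strsplit(consistent$chain[i], ",", fixed = TRUE)[[1]]
    expect_equal(chain_support(chain, tx), consistent$support[i],
                 info = consistent$chain[i])
  }
  # the stored (B,C) = 2 is a documented discrepancy: contiguous counting
  # over {(B,C),(A,B,C),(B,C,D),(A,B,C,D)} gives 4
  expect_equal(chain_support(c("B", "C"), tx), 4L)
  expect_equal(wx$support$support[wx$support$chain == "B,C"], 2L)
  expect_true(wx$support$known_discrepancy[wx$support$chain == "B,C"])
  # non-contiguous order never counts; absent genes give zero
  expect_equal(chain_support(c("B", "D"), tx), 0L)
  expect_equal(chain_support("Z", tx), 0L)
})

test_that("apriori reproduces the worked-example trace at min_support 3", {
  st <- apriori(wx_transactions(), min_support = 3)
  Fk <- vapply(st$F, paste, character(1L), collapse = " ")
  # level 1: all four singletons frequent, nothing infrequent
  expect_true(all(c("A", "B", "C", "D") %in% Fk))
  expect_identical(st$trace[[1]]$removed_next, character(0))
  # level 2: (A,B) and (C,D) frequent, (A,C) and (A,D) infrequent
  expect_true(all(c("A B", "C D") %in% Fk))
  Fbark <- vapply(st$Fbar, paste, character(1L), collapse = " ")
  expect_true(all(c("A C", "A D") %in% Fbark))
  # (A,C,D) is pruned from level 3 before scoring (superset of (A,C))
  expect_true("A\tC\tD" %in% st$trace[[2]]$removed_next)
  expect_false("A\tC\tD" %in% names(st$trace[[3]]$support))
  # consequence of the contiguous rule: (B,C) has support 4 and is frequent,
  # so (B,C,D) survives to level 3 (diverging from the stored reference trace)
  expect_true("B C" %in% Fk)
  expect_true("B\tC\tD" %in% names(st$trace[[3]]$support))
  # F and Fbar partition the scored candidates
  expect_length(intersect(Fk, Fbark), 0L)
  expect_true(all(st$support[vapply(st$F, gsear:::.chain_key, character(1))]
                  >= 3L))
  expect_true(all(st$support[vapply(st$Fbar, gsear:::.chain_key, character(1))]
                  < 3L))
})

test_that("anti-monotonicity holds on worked-example outputs", {
  tx <- wx_transactions()
  chains <- unlist(unclass(tx), recursive = FALSE)
  for (t in chains) {
    n <- length(t)
    for (a in seq_len(n)) for (b in a:n) {
      sub <- t[a:b]
      expect_gte(chain_support(sub, tx), chain_support(t, tx))
    }
  }
})

test_that("apriori equals brute-force enumerate-and-threshold on random graphs", {
  set.seed(31)
  for (rep in 1:60) {
    k <- sample(4:10, 1)
    g <- build_graph(random_graph_records(k, runif(1, 0.1, 0.3)))
    genes <- LETTERS[seq_len(k)]
    tx <- generate_transactions(genes, g, max_len = 4)
    min_s <- sample(2:4, 1)
    st <- apriori(tx, min_support = min_s)
    want <- oracle_frequent(unlist(unclass(tx), recursive = FALSE), min_s)
    expect_identical(chain_keys(st$F), chain_keys(want$chains))
  }
})

test_that("d = delta M matches the reference closed forms", {
  wx <- worked_example()
  g <- wx_graph()
  # 2-chain (A,B) with A -> B: d = (a, a+b)
  M2 <- correlation_matrix(c("A", "B"), g)
  set.seed(41)
  for (rep in 1:30) {
    ab <- rnorm(2)
    expect_equal(d_statistic(ab, M2), c(ab[1], ab[1] + ab[2]),
                 tolerance = 1e-12)
  }
  # 4-tuple closed form (a, a+b, -a-b+c, a+c+d)
  M4 <- correlation_matrix(c("A", "B", "C", "D"), g)
  for (rep in 1:30) {
    dl <- rnorm(4, sd = 2)
    expect_equal(d_statistic(dl, M4), wx$d_closed_form(dl), tolerance = 1e-12)
  }
  expect_equal(d_statistic(c(1, 1, 1, 1), M4), c(1, 2, -1, 3))
  expect_error(d_statistic(c(1, 2), M4), "dimension")
})

test_that("the norm of d behaves as specified", {
  expect_equal(d_norm(c(1, 2, -1, 3)), sqrt(15))
  expect_equal(d_norm(numeric(3)), 0)
  set.seed(42)
  for (s in rnorm(10)) expect_equal(d_norm(d_statistic(s, matrix(1))), abs(s))
})

test_that("d is linear in delta and its norm respects consistent reordering", {
  g <- wx_graph()
  M <- correlation_matrix(c("A", "B", "C", "D"), g)
  set.seed(43)
  for (rep in 1:20) {
    d1 <- rnorm(4); d2 <- rnorm(4); a <- rnorm(1); b <- rnorm(1)
    expect_equal(d_statistic(a * d1 + b * d2, M),
                 a * d_statistic(d1, M) + b * d_statistic(d2, M),
                 tolerance = 1e-10)
    perm <- sample(4)
    tuple <- c("A", "B", "C", "D")[perm]
    expect_equal(d_norm(d_statistic(d1[perm], correlation_matrix(tuple, g))),
                 d_norm(d_statistic(d1, M)), tolerance = 1e-10)
  }
})

test_that("concordant expression outweighs discordant for an activating pair", {
  g <- build_graph(interaction_records("X", "Y", 1L))
  M <- correlation_matrix(c("X", "Y"), g)
  set.seed(44)
  for (rep in 1:50) {
    x <- runif(1, 0.01, 5); y <- runif(1, 0.01, 5)
    expect_gt(d_norm(d_statistic(c(x, y), M)),
              d_norm(d_statistic(c(x, -y), M)))
  }
})

test_that("frequent chains rank by descending norm within each cardinality only", {
  recs <- data.frame(cardinality = c(2L, 2L, 3L, 2L))
  recs$chain <- list(c("B", "C"), c("A", "B"), c("A", "B", "C"), c("A", "C"))
  recs$d_norm <- c(3.0, 1.0, 0.5, 3.0)
  recs$support <- c(4L, 3L, 3L, 3L)
  recs$d_vector <- list(0, 0, 0, 0)
  out <- rank_frequent(recs)
  two <- out[out$cardinality == 2L, ]
  # ties at 3.0 break lexicographically: (A,C) before (B,C)
  expect_identical(vapply(two$chain, paste, character(1), collapse = ""),
                   c("AC", "BC", "AB"))
  expect_identical(two$rank_within_cardinality, 1:3)
  expect_identical(out$rank_within_cardinality[out$cardinality == 3L], 1L)
})

test_that("refine composes the stages deterministically", {
  g <- wx_graph()
  l <- data.frame(gene = c("A", "B", "C", "D"), delta = c(1, 1, 1, 1))
  out <- refine(l, g, min_support = 3)
  expect_s3_class(out, "frequent_sets")
  singles <- out[out$cardinality == 1L, ]
  # all deltas equal: frequent singletons tie at ||d|| = 1
  expect_equal(singles$d_norm, rep(1, 4))
  expect_identical(vapply(singles$chain, paste, character(1)),
                   c("A", "B", "C", "D"))  # lexicographic tie-break
  # supports carried through from the mining stage
  expect_equal(out$support[vapply(out$chain, paste, character(1),
                                  collapse = ",") == "A,B"], 3L)
  out2 <- refine(l, g, min_support = 3)
  expect_identical(out[, names(out) != "d_vector"],
                   out2[, names(out2) != "d_vector"])
  expect_equal(out$d_vector, out2$d_vector)

  empty <- refine(data.frame(gene = character(0), delta = numeric(0)), g)
  expect_equal(nrow(empty), 0L)
})

test_that("a planted concordant chain tops its cardinality group", {
  # strong concordant 3-chain X->Y->Z among weak background chains
  set.seed(51)
  genes <- c("X", "Y", "Z", "U", "V", paste0("n", 1:6))
  recs <- interaction_records(
    source = c("X", "Y", "U", "V", "n1", "n2", "n3", "n4"),
    target = c("Y", "Z", "X", "X", "n2", "n3", "n4", "n1"),
    sign   = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  g <- build_graph(recs)
  delta <- c(X = 3, Y = 3.2, Z = 2.8, U = 2.5, V = 2.4,
             n1 = 0.2, n2 = -0.1, n3 = 0.15, n4 = 0.05, n5 = 0.1, n6 = 0.1)
  l <- data.frame(gene = genes, delta = unname(delta[genes]))
  out <- refine(l, g, min_support = 3, max_len = 4)
  three <- out[out$cardinality == 3L, ]
  expect_true(nrow(three) >= 1L)
  top <- three[three$rank_within_cardinality == 1L, ]
  expect_identical(top$chain[[1]], c("X", "Y", "Z"))
})
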