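test_that("pair test matches the closed-form hypergeometric value", {
  pres <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10),
                                           c("a", "b", "c")))
  pres[1:5, "a"] <- 1; pres[1:5, "b"] <- 1
  pres[6:10, "c"] <- 1
  pt <- pair_test(pres, "a", "b")
  expect_equal(pt$k, 5)
  expect_equal(pt$expected, 2.5)
  expect_equal(pt$p_more, 1 / 252)
  # perfect complementarity: p_less symmetric
  pt2 <- pair_test(pres, "a", "c")
  expect_equal(pt2$k, 0)
  expect_equal(pt2$p_less, 1 / 252)
  # degenerate margin
  pres[, "a"] <- 1
  expect_error(pair_test(pres, "a", "b"), "degenerate margin")
})

test_that("pair tests match exhaustive enumeration of placements", {
  # oracle: enumerate all C(N, nA) placements of taxon A against a fixed
  # placement of B; P(X >= k) by counting
  enum_p <- function(N, nA, nB, k, tail = "more") {
    combos <- combn(N, nA)
    b <- seq_len(nB)
    ov <- apply(combos, 2, function(a) length(intersect(a, b)))
    if (tail == "more") mean(ov >= k) else mean(ov <= k)
  }
  set.seed(8)
  for (rep in 1:20) {
    N <- sample(6:12, 1)
    nA <- sample(1:(N - 1), 1)
    nB <- sample(1:(N - 1), 1)
    k <- sample(max(0, nA + nB - N):min(nA, nB), 1)
    expect_equal(
      stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE),
      enum_p(N, nA, nB, k, "more"), tolerance = 1e-12)
    expect_equal(stats::phyper(k, nA, N - nA, nB),
                 enum_p(N, nA, nB, k, "less"), tolerance = 1e-12)
  }
})

test_that("metanetwork signs, prevalence filter and invariances hold", {
  set.seed(14)
  n <- 40
  pres <- matrix(rbinom(n * 8, 1, 0.5), n, 8,
                 dimnames = list(paste0("s", 1:n), paste0("t", 1:8)))
  pres[, 2] <- pres[, 1]                 # perfect co-occurrence
  pres[, 4] <- 1 - pres[, 3]             # perfect co-exclusion
  pres[, 8] <- c(rep(1, 2), rep(0, n - 2))  # fails min_prevalence
  ct <- count_table(pres, "16S")
  mn <- build_metanetwork(ct, depth = NULL, q_threshold = 0.05,
                          min_prevalence = 5)
  expect_true("t8" %in% mn$skipped)
  key <- paste(mn$edges$node_a, mn$edges$node_b)
  expect_true("t1 t2" %in% key)
  expect_identical(mn$edges$sign[key == "t1 t2"], "+")
  expect_true("t3 t4" %in% key)
  expect_identical(mn$edges$sign[key == "t3 t4"], "-")
  # sign condition: + iff k > expected, - iff k < expected
  expect_true(all(mn$edges$k[mn$edges$sign == "+"] >
                    mn$edges$expected[mn$edges$sign == "+"]))
  expect_true(all(mn$edges$k[mn$edges$sign == "-"] <
                    mn$edges$expected[mn$edges$sign == "-"]))
  expect_true(all(mn$edges$q < 0.05))
  # invariance to sample and taxon order
  perm_s <- sample(n); perm_t <- sample(8)
  ct2 <- count_table(pres[perm_s, perm_t], "16S")
  mn2 <- build_metanetwork(ct2, depth = NULL, q_threshold = 0.05,
                           min_prevalence = 5)
  canon <- function(e) {
    k <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b), e$sign)
    sort(k)
  }
  expect_identical(canon(mn2$edges), canon(mn$edges))
  expect_error(build_metanetwork(
    count_table(pres[, 1:3], "16S"), depth = NULL, min_prevalence = 30),
    "fewer than 3 taxa")
})

test_that("swap null model reproduces the analytic verdicts on strong pairs", {
  set.seed(23)
  n <- 30
  pres <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                 dimnames = list(paste0("s", 1:n), paste0("t", 1:6)))
  pres[, 2] <- pres[, 1]
  ct <- count_table(pres, "16S")
  mn <- build_metanetwork(ct, depth = NULL, null_model = "swap",
                          n_null = 500, q_threshold = 0.15,
                          min_prevalence = 5, seed = 5)
  key <- paste(mn$edges$node_a, mn$edges$node_b)
  expect_true("t1 t2" %in% key)
  expect_identical(mn$edges$sign[key == "t1 t2"], "+")
})

test_that("local properties match hand values on canonical subgraphs", {
  # build a metanetwork-shaped object directly
  tri_edges <- data.frame(node_a = c("a", "a", "b"),
                          node_b = c("b", "c", "c"),
                          sign = "+", weight = 1, p = 0.01, q = 0.01,
                          stringsAsFactors = FALSE)
  mn <- structure(list(marker = "16S", edges = tri_edges,
                       taxa = c("a", "b", "c", "d"),
                       presence = NULL, n_tests = 6L,
                       skipped = character(0)), class = "metanetwork")
  m <- matrix(1, 1, 4, dimnames = list("s1", c("a", "b", "c", "d")))
  ct <- count_table(m, "16S")
  lp <- local_properties(mn, ct, "s1", sign = "+", seed = 1)
  expect_equal(lp$transitivity, 1)
  expect_equal(lp$average_path_length, 1)
  expect_equal(lp$n_edges, 3)
  # 3-node path: transitivity 0, APL 4/3
  path_edges <- tri_edges[1:2, ]   # a-b, a-c
  mn$edges <- path_edges
  lp2 <- local_properties(mn, ct, "s1", sign = "+", seed = 1)
  expect_equal(lp2$transitivity, 0)
  expect_equal(lp2$average_path_length, 4 / 3)
  # co-exclusion sign absent -> all properties missing
  lp3 <- local_properties(mn, ct, "s1", sign = "-", seed = 1)
  expect_true(is.na(lp3$modularity) && is.na(lp3$transitivity) &&
                is.na(lp3$average_path_length))
  expect_error(local_properties(mn, ct, "nope"), "unknown sample")
})

test_that("two disjoint 3-cliques give Louvain Q = 0.5", {
  cl <- expand.grid(a = c("a1", "a2", "a3"), b = c("a1", "a2", "a3"))
  e1 <- data.frame(node_a = c("a1", "a1", "a2", "b1", "b1", "b2"),
                   node_b = c("a2", "a3", "a3", "b2", "b3", "b3"),
                   sign = "+", weight = 1, p = 0.01, q = 0.01,
                   stringsAsFactors = FALSE)
  mn <- structure(list(marker = "16S", edges = e1,
                       taxa = c("a1", "a2", "a3", "b1", "b2", "b3"),
                       presence = NULL, n_tests = 2L,
                       skipped = character(0)), class = "metanetwork")
  m <- matrix(1, 1, 6,
              dimnames = list("s1", c("a1", "a2", "a3", "b1", "b2", "b3")))
  lp <- local_properties(mn, count_table(m, "16S"), "s1", sign = "+",
                         seed = 4)
  # direct evaluation of Q = sum(e_ii - a_i^2) with the cliques as modules
  adj <- matrix(0, 6, 6, dimnames = list(colnames(m), colnames(m)))
  for (r in seq_len(nrow(e1))) {
    adj[e1$node_a[r], e1$node_b[r]] <- adj[e1$node_b[r], e1$node_a[r]] <- 1
  }
  expect_equal(oracle_modularity_of(adj, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(lp$modularity, 0.5)
})

test_that("isolated present taxa do not change transitivity or APL", {
  set.seed(33)
  adj <- random_connected_adj(6, 0.5)
  e <- adj_to_edges(adj)
  taxa <- paste0("v", 1:6)
  mn <- structure(list(marker = "16S", edges = e, taxa = c(taxa, "iso"),
                       presence = NULL, n_tests = 2L,
                       skipped = character(0)), class = "metanetwork")
  m1 <- matrix(1, 1, 6, dimnames = list("s1", taxa))
  m2 <- matrix(1, 1, 7, dimnames = list("s1", c(taxa, "iso")))
  lp1 <- local_properties(mn, count_table(m1, "16S"), "s1", seed = 2)
  lp2 <- local_properties(mn, count_table(m2, "16S"), "s1", seed = 2)
  expect_equal(lp1$transitivity, lp2$transitivity)
  expect_equal(lp1$average_path_length, lp2$average_path_length)
  expect_equal(lp2$n_nodes, lp1$n_nodes + 1)
})

test_that("local_properties_all composes per-sample calls deterministically", {
  tr <- small_trial(seed = 12, n_loc = 3, reps = 2, n_taxa = 25,
                    libs = c(900, 1000))
  rt <- rarefy(tr$counts[["16S"]], 900, seed = 2)
  mn <- build_metanetwork(rt, depth = NULL, min_prevalence = 3)
  all1 <- local_properties_all(list("16S" = mn), list("16S" = rt), seed = 7)
  all2 <- local_properties_all(list("16S" = mn), list("16S" = rt), seed = 7)
  expect_identical(all1, all2)
  expect_equal(nrow(all1), 2 * nrow(ct_counts(rt)))
  s <- ct_samples(rt)[1]
  single <- local_properties(mn, rt, s, sign = "+",
                             seed = potatonet:::derive_seed(
                               7, paste("16S", s, "+")))
  row <- all1[all1$sample_id == s & all1$sign == "+", ]
  expect_equal(row$transitivity, single$transitivity)
  expect_equal(row$modularity, single$modularity)
  wide <- local_properties_wide(all1)
  expect_true("16S_cooccur_transitivity" %in% names(wide))
  expect_equal(nrow(wide), nrow(ct_counts(rt)))
})
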