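test_that("spearman network: monotone pairs, no self edges, invariance", {
  set.seed(41)
  n <- 30
  x <- rnorm(n)
  vars <- data.frame(x = x, y = exp(2 * x), z = rnorm(n), w = rnorm(n))
  net <- spearman_network(vars, min_n = 8, seed = 1)
  e <- net$edges
  key <- paste(e$node_a, e$node_b)
  expect_true("x y" %in% key)
  expect_equal(e$rho[key == "x y"], 1)
  expect_false(any(e$node_a == e$node_b))
  # invariance under strictly monotone transform of a variable
  vars2 <- vars; vars2$z <- qlogis(pnorm(vars2$z))  # monotone
  net2 <- spearman_network(vars2, min_n = 8, seed = 1)
  expect_equal(net2$all_pairs$rho, net$all_pairs$rho, tolerance = 1e-12)
  # constant variable dropped with warning
  vars3 <- vars; vars3$flat <- 5
  expect_warning(spearman_network(vars3, seed = 1), "flat")
})

test_that("louvain recovers two planted correlation blocks", {
  hits <- vapply(1:10, function(i) {
    set.seed(500 + i)
    n <- 40
    f1 <- rnorm(n); f2 <- rnorm(n)
    vars <- data.frame(
      a1 = f1 + rnorm(n, 0, 0.3), a2 = f1 + rnorm(n, 0, 0.3),
      a3 = f1 + rnorm(n, 0, 0.3),
      b1 = f2 + rnorm(n, 0, 0.3), b2 = f2 + rnorm(n, 0, 0.3),
      b3 = f2 + rnorm(n, 0, 0.3))
    net <- spearman_network(vars, min_n = 8, seed = i)
    cl <- net$nodes$cluster
    names(cl) <- net$nodes$node
    length(unique(cl[1:3])) == 1 && length(unique(cl[4:6])) == 1 &&
      cl[["a1"]] != cl[["b1"]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("neighborhood extraction follows the adjacency", {
  e <- data.frame(node_a = c("hub", "hub", "hub", "x"),
                  node_b = c("a", "b", "c", "y"),
                  sign = "+", weight = 0.5, p = 0.01, q = 0.02,
                  rho = 0.5, n_used = 20, stringsAsFactors = FALSE)
  net <- structure(list(edges = e,
                        nodes = data.frame(node = c("hub", "a", "b", "c",
                                                    "x", "y", "lone"),
                                           category = NA, cluster = NA),
                        all_pairs = e, threshold_mode = "fdr",
                        threshold = 0.05), class = "assoc_network")
  nb <- neighborhood(net, "hub")
  expect_setequal(nb$nodes$node, c("hub", "a", "b", "c"))
  expect_equal(nrow(nb$edges), 3)
  lone <- neighborhood(net, "lone")
  expect_equal(nrow(lone$edges), 0)
  expect_identical(lone$nodes$node, "lone")
  leaf <- neighborhood(net, "y")
  expect_setequal(leaf$nodes$node, c("y", "x"))
  expect_error(neighborhood(net, "zzz"), "unknown node")
})

test_that("genus network preprocessing filters, scales and encodes", {
  tr <- small_trial(seed = 19, n_loc = 3, reps = 2, n_taxa = 30,
                    libs = c(2000, 2400))
  prep <- genus_network_preprocess(tr$counts[["16S"]],
                                   tr$taxonomy[["16S"]], tr$frame,
                                   depth = 2000, min_prevalence_frac = 0.2,
                                   seed = 4)
  gm <- ct_counts(prep$genus_table)
  expect_equal(unname(rowSums(gm)), rep(2000, nrow(gm)))  # totals preserved
  expect_true("g__filtered" %in% colnames(gm))
  prev <- colMeans(gm[, prep$kept_genera, drop = FALSE] > 0)
  expect_true(all(prev >= 0.2))
  md <- prep$metadata
  # one-hot block sums to group sizes
  fr <- as.data.frame(tr$frame)
  fr <- fr[match(rownames(md), fr$sample_id), ]
  for (l in unique(fr$location)) {
    expect_equal(sum(md[, paste0("location_", l)]), sum(fr$location == l))
  }
  expect_equal(sum(md[, "treatment_treated"]),
               sum(fr$treatment == "treated"))
  # scaled numeric columns have mean ~0 sd ~1
  expect_lt(abs(mean(md[, "soil_ca"])), 1e-10)
  expect_equal(sd(md[, "soil_ca"]), 1)
})

test_that("prevalence threshold boundary: genus in 1 of 10 samples is cut", {
  m <- matrix(10, 10, 3, dimnames = list(paste0("s", 1:10),
                                         paste0("g", 1:3)))
  m[, 3] <- c(10, rep(0, 9))          # prevalence 0.1 < 0.2
  m[1, 1] <- 20                        # keep totals unequal
  ct <- count_table(m, "16S")
  tax <- taxonomy_table(data.frame(taxon_id = paste0("g", 1:3),
                                   genus = paste0("g", 1:3)), "16S")
  fr <- sample_frame(data.frame(sample_id = paste0("s", 1:10),
                                location = rep(c("A", "B"), 5),
                                treatment = rep(c("control", "treated"), 5),
                                timepoint = "T0", val = rnorm(10)))
  prep <- genus_network_preprocess(ct, tax, fr, depth = 20,
                                   min_prevalence_frac = 0.2, seed = 1)
  expect_false("g3" %in% prep$kept_genera)
  expect_true(all(c("g1", "g2") %in% prep$kept_genera))
})

test_that("degree test: regular graphs give zero differences, p = 1", {
  # 4-cycle: all degrees 2, equal prevalence
  e <- data.frame(node_a = c("a", "b", "c", "d"),
                  node_b = c("b", "c", "d", "a"),
                  sign = "+", weight = 1, p = 0.01, q = 0.01,
                  stringsAsFactors = FALSE)
  prev <- c(a = 0.5, b = 0.5, c = 0.5, d = 0.5)
  res <- degree_prevalence_test(e, prev, n_perm = 99, seed = 1)
  expect_true(all(res$difference == 0))
  expect_true(all(res$p == 1))
  # arbitrary balanced 2-coloring of a regular graph
  grp <- c(a = "red", b = "blue", c = "red", d = "blue")
  res2 <- degree_prevalence_test(e, prev, grouping = grp, n_perm = 99,
                                 seed = 1)
  expect_true(all(res2$difference == 0))
  expect_error(degree_prevalence_test(e, c(a = 0, b = 1, c = 1, d = 1)),
               "prevalence")
})

test_that("degree test detects a planted hub clade", {
  hits <- vapply(1:10, function(i) {
    set.seed(700 + i)
    n <- 100
    g <- igraph::sample_gnp(n, 0.06)
    igraph::V(g)$name <- paste0("n", 1:n)
    # inflate 5 nodes by wiring each to 10 extra distinct partners
    hub <- paste0("n", 1:5)
    for (h in hub) {
      tgt <- sample(setdiff(igraph::V(g)$name,
                            c(h, igraph::V(g)$name[igraph::neighbors(
                              g, h)])), 10)
      g <- igraph::add_edges(g, rbind(rep(h, 10), tgt))
    }
    el <- igraph::as_edgelist(g)
    e <- data.frame(node_a = el[, 1], node_b = el[, 2], sign = "+",
                    weight = 1, p = 0.01, q = 0.01,
                    stringsAsFactors = FALSE)
    prev <- stats::setNames(rep(0.5, n), paste0("n", 1:n))
    grp <- stats::setNames(ifelse(paste0("n", 1:n) %in% hub, "hub",
                                  "rest"), paste0("n", 1:n))
    res <- degree_prevalence_test(e, prev, grouping = grp, n_perm = 499,
                                  seed = i)
    res$p[res$unit == "hub"] < 0.05 &&
      res$difference[res$unit == "hub"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("centrality summary matches closed forms and conserves degree", {
  # star graph: center betweenness (n-1)(n-2)/2
  n <- 6
  e <- data.frame(node_a = "hub", node_b = paste0("x", 1:(n - 1)),
                  sign = "+", weight = 1, p = 0.01, q = 0.01,
                  stringsAsFactors = FALSE)
  cs <- centrality_summary(e)
  expect_equal(cs$nodes$betweenness[cs$nodes$node == "hub"],
               (n - 1) * (n - 2) / 2)
  # P3 middle node betweenness 1
  e3 <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"), sign = "+",
                   weight = 1, p = 0.01, q = 0.01, stringsAsFactors = FALSE)
  cs3 <- centrality_summary(e3)
  expect_equal(cs3$nodes$betweenness[cs3$nodes$node == "b"], 1)
  # clade totals sum to grand total degree
  grp <- c(hub = "A", stats::setNames(rep(c("A", "B"), length.out = n - 1),
                                      paste0("x", 1:(n - 1))))
  cs2 <- centrality_summary(e, grouping = grp)
  expect_equal(sum(cs2$clades$total_degree), sum(cs2$nodes$degree))
})
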