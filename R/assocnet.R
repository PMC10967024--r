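#' Spearman association network across trial variables
#'
#' Pairwise Spearman correlations (average ranks for ties, two-sided p
#' from the t approximation; optional exact permutation p for small n) on
#' pairwise-complete observations, Benjamini-Hochberg correction across
#' all pairs, edge retention by q (default) or raw p, and Louvain
#' clustering of the positive-edge subgraph weighted by |rho|.
#'
#' @param vars data.frame of numeric variables (one row per sample);
#'   constant or all-missing variables are dropped with a warning.
#' @param categories optional named character vector tagging variables
#'   (biodiversity, network-property, yield, soil, petiole, peel,
#'   environment).
#' @param min_n minimum pairwise-complete observations (default 8).
#' @param threshold_mode `"fdr"` (BH q) or `"p"` (raw p, as in a
#'   figure-style p < 0.05 reading).
#' @param threshold cutoff (default 0.05).
#' @param exact_perm_n below this pairwise n, use an exact permutation
#'   p-value (default 0 = never).
#' @param n_perm permutations for the exact option.
#' @param seed RNG seed (Louvain, permutation p-values).
#' @return list of class `assoc_network`: `edges` (canonical columns plus
#'   `rho`, `n_used`), `nodes` (data.frame: node, category, cluster; NA
#'   cluster for isolated nodes), `all_pairs` (every tested pair).
#' @export
spearman_network <- function(vars, categories = NULL, min_n = 8,
                             threshold_mode = c("fdr", "p"),
                             threshold = 0.05, exact_perm_n = 0,
                             n_perm = 999, seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  vars <- as.data.frame(vars)
  keep <- vapply(vars, function(v) {
    is.numeric(v) && sum(!is.na(v)) >= 2 && stats::sd(v, na.rm = TRUE) > 0
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant or non-numeric variable(s): ",
            paste(names(vars)[!keep], collapse = ", "))
  }
  vars <- vars[, keep, drop = FALSE]
  nm <- names(vars)
  np <- length(nm)
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(np - 1)) {
      for (j in seq((i + 1), np)) {
        x <- vars[[i]]; y <- vars[[j]]
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        if (n < min_n) next
        xr <- rank(x[ok]); yr <- rank(y[ok])
        if (stats::sd(xr) == 0 || stats::sd(yr) == 0) next
        rho <- stats::cor(xr, yr)
        p <- if (exact_perm_n > 0 && n < exact_perm_n) {
          ex <- 0L
          for (b in seq_len(n_perm)) {
            if (abs(stats::cor(sample(xr), yr)) >= abs(rho) - 1e-12) {
              ex <- ex + 1L
            }
          }
          (1 + ex) / (1 + n_perm)
        } else {
          spearman_p_t(rho, n)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(node_a = nm[i], node_b = nm[j], rho = rho, p = p,
                     n_used = n, stringsAsFactors = FALSE)
      }
    }
  })
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_a = character(0), node_b = character(0),
               rho = numeric(0), p = numeric(0), n_used = integer(0))
  pairs$q <- stats::p.adjust(pairs$p, method = "BH")
  crit <- if (threshold_mode == "fdr") pairs$q else pairs$p
  sel <- !is.na(crit) & crit < threshold
  edges <- pairs[sel, , drop = FALSE]
  edges <- data.frame(node_a = edges$node_a, node_b = edges$node_b,
                      sign = ifelse(edges$rho >= 0, "+", "-"),
                      weight = edges$rho, p = edges$p, q = edges$q,
                      rho = edges$rho, n_used = edges$n_used,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL

  nodes <- data.frame(node = nm, stringsAsFactors = FALSE)
  nodes$category <- if (is.null(categories)) NA_character_ else
    unname(categories[nodes$node])
  nodes$cluster <- NA_integer_
  pos <- edges[edges$sign == "+", , drop = FALSE]
  if (nrow(pos)) {
    g <- edges_to_igraph(pos)
    igraph::E(g)$weight <- abs(pos$rho)
    cl <- with_seed(derive_seed(seed, "louvain"),
                    igraph::cluster_louvain(g))
    memb <- igraph::membership(cl)
    nodes$cluster[match(names(memb), nodes$node)] <- as.integer(memb)
  }
  structure(list(edges = edges, nodes = nodes, all_pairs = pairs,
                 threshold_mode = threshold_mode, threshold = threshold),
            class = "assoc_network")
}

# Two-sided Spearman p-value via the t approximation.
spearman_p_t <- function(rho, n) {
  if (abs(rho) >= 1) return(2 / choose(n, 2))  # tied-rank-free bound
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> %d nodes, %d edges (%s < %g), %d clusters\n",
              nrow(x$nodes), nrow(x$edges), x$threshold_mode, x$threshold,
              length(unique(stats::na.omit(x$nodes$cluster)))))
  invisible(x)
}

#' Direct neighborhood of a node
#'
#' Induced subnetwork on a node and its direct neighbors, edge
#' annotations preserved (e.g. the neighborhood of yield).
#'
#' @param network an `assoc_network`.
#' @param node node name.
#' @return an `assoc_network` restricted to the neighborhood.
#' @export
neighborhood <- function(network, node) {
  abort_if(!node %in% network$nodes$node,
           sprintf("unknown node '%s'", node))
  e <- network$edges
  touch <- e$node_a == node | e$node_b == node
  nbrs <- unique(c(node, e$node_a[touch], e$node_b[touch]))
  keep <- e$node_a %in% nbrs & e$node_b %in% nbrs
  structure(list(edges = e[keep, , drop = FALSE],
                 nodes = network$nodes[network$nodes$node %in% nbrs, ,
                                       drop = FALSE],
                 all_pairs = network$all_pairs,
                 threshold_mode = network$threshold_mode,
                 threshold = network$threshold),
            class = "assoc_network")
}

#' Preprocess genus tables and metadata for global network inference
#'
#' Mirrors the preprocessing applied before conditional-independence
#' network inference (e.g. FlashWeave): genus aggregation, rarefaction at
#' the marker-specific depth (samples below depth dropped), a prevalence
#' filter (default 20%) with removed genera pooled into a remainder
#' category `g__filtered` so per-sample totals are preserved, numeric
#' metadata centered and scaled, and location/treatment expanded to
#' one-hot indicator columns.
#'
#' @param table ASV [count_table].
#' @param tax matching [taxonomy_table].
#' @param frame a [sample_frame].
#' @param depth rarefaction depth (default 10000 for 16S, 18750 for ITS).
#' @param min_prevalence_frac prevalence threshold (default 0.2).
#' @param numeric_vars names of numeric metadata columns to scale
#'   (default: all numeric columns).
#' @param seed RNG seed.
#' @return list: `genus_table` (filtered [count_table] incl. remainder
#'   category), `metadata` (scaled numeric block + one-hot columns,
#'   rownames = sample ids), `kept_genera`, `dropped_samples`.
#' @export
genus_network_preprocess <- function(table, tax, frame, depth = NULL,
                                     min_prevalence_frac = 0.2,
                                     numeric_vars = NULL, seed = 1L) {
  depth <- depth %||% default_depth(table$marker)
  gt <- aggregate_to_genus(table, tax)
  rt <- rarefy(gt, depth, seed = seed)
  dropped <- attr(rt, "dropped")
  m <- ct_counts(rt)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence_frac
  abort_if(!any(keep), "no genera pass the prevalence filter")
  filtered <- m[, keep, drop = FALSE]
  remainder <- rowSums(m[, !keep, drop = FALSE])
  out <- cbind(filtered, g__filtered = remainder)
  gt2 <- count_table(out, table$marker)

  fr <- as.data.frame(frame)
  fr <- fr[match(rownames(out), fr$sample_id), , drop = FALSE]
  numeric_vars <- numeric_vars %||%
    names(fr)[vapply(fr, is.numeric, logical(1))]
  blocks <- list()
  for (nm in numeric_vars) {
    v <- fr[[nm]]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warning(sprintf("constant metadata column '%s' dropped", nm))
      next
    }
    blocks[[nm]] <- as.numeric(scale(v))
  }
  md <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow(fr), 0)
  onehot <- function(x, prefix) {
    levs <- sort(unique(x))
    out <- vapply(levs, function(l) as.numeric(x == l),
                  numeric(length(x)))
    colnames(out) <- paste(prefix, levs, sep = "_")
    out
  }
  md <- cbind(md, onehot(fr$location, "location"),
              onehot(fr$treatment, "treatment"))
  rownames(md) <- fr$sample_id
  list(genus_table = gt2, metadata = md,
       kept_genera = colnames(filtered), dropped_samples = dropped)
}

default_depth <- function(marker) {
  switch(marker, "16S" = 10000L, "ITS" = 18750L,
         stop(sprintf("no default depth for marker '%s'", marker)))
}

#' Prevalence-conditional degree permutation test
#'
#' Identifies taxa (or clades) whose total degree in a signed network is
#' higher or lower than expected given their prevalence. Expected degree
#' per node is the mean degree of its prevalence bin (equal-frequency
#' bins; singleton bins are merged into their neighbor); the unit
#' statistic is the sum of observed minus expected over member nodes; the
#' null permutes node degrees within prevalence bins.
#' `p = (1 + #[|null| >= |obs|]) / (1 + n_perm)` (two-sided).
#'
#' @param edges edge data.frame (any signed genus network, e.g. imported
#'   FlashWeave output read with [read_edges()]).
#' @param prevalence named numeric vector in (0, 1], one per node.
#' @param grouping `NULL` (per node) or a named character vector mapping
#'   node -> clade (e.g. phylum or class).
#' @param n_bins prevalence bins (default 10).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return data.frame: unit, n_nodes, observed, expected, difference, p.
#' @export
degree_prevalence_test <- function(edges, prevalence, grouping = NULL,
                                   n_bins = 10, n_perm = 1000, seed = 1L) {
  abort_if(is.null(names(prevalence)), "prevalence must be named by node")
  abort_if(any(prevalence <= 0 | prevalence > 1),
           "prevalence must be in (0, 1]")
  nodes <- names(prevalence)
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(factor(c(edges$node_a, edges$node_b), levels = nodes))
    deg[] <- as.numeric(tab)
  }
  # equal-frequency bins with singleton-merge
  qs <- stats::quantile(prevalence, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 1)
  bin <- findInterval(prevalence, unique(qs), rightmost.closed = TRUE)
  repeat {
    sizes <- table(bin)
    small <- names(sizes)[sizes < 2]
    if (length(small) == 0 || length(sizes) == 1) break
    b <- as.integer(small[1])
    neigh <- if (any(bin < b)) max(bin[bin < b]) else min(bin[bin > b])
    bin[bin == b] <- neigh
  }
  expected <- stats::ave(deg, bin, FUN = mean)
  units <- if (is.null(grouping)) stats::setNames(nodes, nodes) else {
    abort_if(!all(nodes %in% names(grouping)),
             "grouping must cover every node")
    grouping[nodes]
  }
  ulev <- unique(unname(units))
  obs_stat <- vapply(ulev, function(u) {
    sum(deg[units == u] - expected[units == u])
  }, numeric(1))
  exceed <- rep(0L, length(ulev))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      dp <- deg
      for (bb in unique(bin)) {
        w <- which(bin == bb)
        dp[w] <- deg[w][sample.int(length(w))]
      }
      null_stat <- vapply(ulev, function(u) {
        sum(dp[units == u] - expected[units == u])
      }, numeric(1))
      exceed <- exceed + as.integer(abs(null_stat) >= abs(obs_stat) - 1e-12)
    }
  })
  data.frame(unit = ulev,
             n_nodes = as.integer(table(units)[ulev]),
             observed = vapply(ulev, function(u) sum(deg[units == u]),
                               numeric(1)),
             expected = vapply(ulev, function(u) sum(expected[units == u]),
                               numeric(1)),
             difference = obs_stat,
             p = (1 + exceed) / (1 + n_perm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Degree and betweenness centrality summary
#'
#' Exact betweenness (all-pairs shortest paths, unweighted) and degree
#' per node, plus total degree per clade when a grouping is given.
#'
#' @param edges edge data.frame.
#' @param grouping optional named character vector node -> clade.
#' @param nodes optional nodes to include even if isolated.
#' @return list: `nodes` (node, degree, betweenness, clade), `clades`
#'   (clade, total_degree) or NULL.
#' @export
centrality_summary <- function(edges, grouping = NULL, nodes = NULL) {
  g <- edges_to_igraph(edges, nodes = unique(c(nodes, names(grouping))))
  nd <- data.frame(node = igraph::V(g)$name,
                   degree = as.numeric(igraph::degree(g)),
                   betweenness = as.numeric(
                     igraph::betweenness(g, directed = FALSE,
                                         weights = NA)),
                   stringsAsFactors = FALSE)
  clades <- NULL
  if (!is.null(grouping)) {
    nd$clade <- unname(grouping[nd$node])
    tg <- tapply(nd$degree, nd$clade, sum)
    clades <- data.frame(clade = names(tg), total_degree = as.numeric(tg),
                         stringsAsFactors = FALSE, row.names = NULL)
  }
  list(nodes = nd, clades = clades)
}
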