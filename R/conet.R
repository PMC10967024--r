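#' Hypergeometric presence-absence pair test
#'
#' Probabilistic co-occurrence test on fixed presence margins: with `N`
#' samples, marginal presences `nA` and `nB` and observed co-presence
#' count `k`, the co-presence count under independence is
#' `X ~ Hypergeometric(N, nA, nB)`, expected value `nA * nB / N`.
#' `p_more = P(X >= k)` supports co-occurrence, `p_less = P(X <= k)`
#' supports co-exclusion. Degenerate margins (0 or N) are untestable.
#'
#' @param presence logical/0-1 matrix, samples x taxa.
#' @param taxon_a,taxon_b column names of the pair.
#' @return list: `k`, `expected`, `p_more`, `p_less`.
#' @export
pair_test <- function(presence, taxon_a, taxon_b) {
  a <- presence[, taxon_a] > 0
  b <- presence[, taxon_b] > 0
  n <- length(a)
  na <- sum(a); nb <- sum(b)
  abort_if(na == 0 || na == n || nb == 0 || nb == n,
           "degenerate margin: taxon present in 0 or all samples")
  k <- sum(a & b)
  list(k = k, expected = na * nb / n,
       p_more = stats::phyper(k - 1, na, n - na, nb, lower.tail = FALSE),
       p_less = stats::phyper(k, na, n - na, nb))
}

# Vectorized pair tests over all qualifying unordered pairs of a presence
# matrix. Returns a data.frame with one row per pair.
all_pair_tests <- function(presence) {
  n <- nrow(presence)
  marg <- colSums(presence)
  K <- crossprod(presence)      # co-presence counts
  taxa <- colnames(presence)
  idx <- which(upper.tri(K), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  k <- K[idx]
  na <- marg[i]; nb <- marg[j]
  data.frame(node_a = taxa[i], node_b = taxa[j], k = k,
             expected = na * nb / n,
             p_more = stats::phyper(k - 1, na, n - na, nb,
                                    lower.tail = FALSE),
             p_less = stats::phyper(k, na, n - na, nb),
             stringsAsFactors = FALSE)
}

# Fixed-margin (checkerboard swap) null: repeatedly exchanges 2x2
# checkerboard submatrices, preserving row and column sums exactly.
checkerboard_swaps <- function(P, nswap) {
  n <- nrow(P); m <- ncol(P)
  done <- 0L; attempts <- 0L; max_attempts <- 200L * nswap
  while (done < nswap && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- sample.int(n, 2); cc <- sample.int(m, 2)
    s11 <- P[r[1], cc[1]]; s12 <- P[r[1], cc[2]]
    s21 <- P[r[2], cc[1]]; s22 <- P[r[2], cc[2]]
    if (s11 == 1 && s22 == 1 && s12 == 0 && s21 == 0) {
      P[r[1], cc[1]] <- 0; P[r[2], cc[2]] <- 0
      P[r[1], cc[2]] <- 1; P[r[2], cc[1]] <- 1
      done <- done + 1L
    } else if (s11 == 0 && s22 == 0 && s12 == 1 && s21 == 1) {
      P[r[1], cc[1]] <- 1; P[r[2], cc[2]] <- 1
      P[r[1], cc[2]] <- 0; P[r[2], cc[1]] <- 0
      done <- done + 1L
    }
  }
  P
}

# Pair p-values from the swap null: proportion of null co-presence counts
# at least as extreme as observed, with add-one smoothing.
swap_null_pair_tests <- function(presence, n_null = 200) {
  tests <- all_pair_tests(presence)  # reuse k/expected bookkeeping
  K_obs <- crossprod(presence)
  ge <- le <- matrix(0L, ncol(presence), ncol(presence))
  nnz <- sum(presence)
  P <- checkerboard_swaps(presence, 5L * nnz)  # burn-in
  for (b in seq_len(n_null)) {
    P <- checkerboard_swaps(P, nnz)
    Kb <- crossprod(P)
    ge <- ge + (Kb >= K_obs)
    le <- le + (Kb <= K_obs)
  }
  idx <- which(upper.tri(K_obs), arr.ind = TRUE)
  tests$p_more <- (1 + ge[idx]) / (1 + n_null)
  tests$p_less <- (1 + le[idx]) / (1 + n_null)
  tests
}

#' Build a signed presence-absence metanetwork
#'
#' Rarefies the marker's count table, derives presence (rarefied count
#' > 0), applies the prevalence pre-filter (present in at least
#' `min_prevalence` and at most `N - min_prevalence` samples so both tails
#' are testable), runs the hypergeometric pair test on every remaining
#' unordered taxon pair, applies Benjamini-Hochberg across the union of
#' both one-sided p-value families, and keeps edges with `q <
#' q_threshold`: sign `+` where observed co-presence exceeds expectation
#' (co-occurrence), `-` where it falls short (co-exclusion).
#'
#' @param table a [count_table] spanning all samples of one marker.
#' @param depth rarefaction depth (`NULL` to skip rarefaction, e.g. for
#'   already-rarefied input).
#' @param seed RNG seed (rarefaction).
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @param min_prevalence minimum (and symmetric maximum) presence count
#'   (default 5).
#' @param null_model `"hypergeometric"` (analytic, default) or `"swap"`
#'   (fixed-margin checkerboard permutation null).
#' @param n_null null matrices for the swap model.
#' @return list of class `metanetwork`: `marker`, `edges` (canonical edge
#'   data.frame with `k`, `expected` extras), `taxa` (tested nodes),
#'   `presence` (the presence matrix used), `n_tests`, `skipped`
#'   (taxa excluded by the pre-filter).
#' @export
build_metanetwork <- function(table, depth = NULL, seed = 1L,
                              q_threshold = 0.05, min_prevalence = 5,
                              null_model = c("hypergeometric", "swap"),
                              n_null = 200) {
  null_model <- match.arg(null_model)
  rt <- if (is.null(depth)) table else rarefy(table, depth, seed = seed)
  m <- ct_counts(rt)
  presence <- (m > 0) * 1
  n <- nrow(presence)
  prev <- colSums(presence)
  ok <- prev >= min_prevalence & prev <= n - min_prevalence
  skipped <- colnames(presence)[!ok]
  presence <- presence[, ok, drop = FALSE]
  abort_if(ncol(presence) < 3, "fewer than 3 taxa after filtering")
  tests <- if (null_model == "swap") {
    with_seed(derive_seed(seed, "swapnull"),
              swap_null_pair_tests(presence, n_null = n_null))
  } else {
    all_pair_tests(presence)
  }
  # BH over the union of the two one-sided families
  pu <- c(tests$p_more, tests$p_less)
  qu <- stats::p.adjust(pu, method = "BH")
  np <- nrow(tests)
  tests$q_more <- qu[seq_len(np)]
  tests$q_less <- qu[np + seq_len(np)]
  pos <- tests$q_more < q_threshold & tests$k > tests$expected
  neg <- tests$q_less < q_threshold & tests$k < tests$expected
  sel <- pos | neg
  edges <- data.frame(node_a = tests$node_a[sel], node_b = tests$node_b[sel],
                      sign = ifelse(pos[sel], "+", "-"),
                      weight = ifelse(pos[sel],
                                      tests$k[sel] - tests$expected[sel],
                                      tests$expected[sel] - tests$k[sel]),
                      p = ifelse(pos[sel], tests$p_more[sel],
                                 tests$p_less[sel]),
                      q = ifelse(pos[sel], tests$q_more[sel],
                                 tests$q_less[sel]),
                      k = tests$k[sel], expected = tests$expected[sel],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(marker = table$marker, edges = edges,
                 taxa = colnames(presence), presence = presence,
                 n_tests = 2L * np, skipped = skipped),
            class = "metanetwork")
}

#' @export
print.metanetwork <- function(x, ...) {
  cat(sprintf(
    "<metanetwork> marker=%s: %d tested taxa, %d '+' / %d '-' edges\n",
    x$marker, length(x$taxa), sum(x$edges$sign == "+"),
    sum(x$edges$sign == "-")))
  invisible(x)
}

# Transitivity / average path length / best-restart Louvain modularity of
# one (sub)graph. Transitivity is 0 when the graph has no connected
# triples; APL and modularity are NA when it has no edges.
graph_props <- function(g, seed = 1L, restarts = 10) {
  n_edges <- igraph::ecount(g)
  if (n_edges == 0) {
    return(list(n_edges = 0L, transitivity = NA_real_,
                average_path_length = NA_real_, modularity = NA_real_))
  }
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  apl <- igraph::mean_distance(g, unconnected = TRUE)
  mod <- with_seed(seed, louvain_modularity(g, restarts = restarts))
  list(n_edges = n_edges, transitivity = trans,
       average_path_length = apl, modularity = mod)
}

# Best-of-R-restarts Louvain modularity on an igraph graph (unweighted).
louvain_modularity <- function(g, restarts = 10) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  best <- -Inf
  for (r in seq_len(restarts)) {
    # randomize vertex processing order between restarts
    perm <- sample.int(igraph::vcount(g))
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    q <- igraph::modularity(cl)
    if (q > best) best <- q
  }
  best
}

#' Per-sample local network properties
#'
#' Subsets the metanetwork to the taxa present in one sample (rarefied
#' count > 0) and the requested edge sign, then computes:
#' * transitivity: 3 x triangles / connected triples, defined 0 when the
#'   subgraph has no connected triples;
#' * average path length: mean shortest-path distance over pairs within
#'   connected components, `NA` when the subgraph has no edges;
#' * modularity: best Louvain `Q` over `restarts` seeded restarts on the
#'   unweighted subgraph, `NA` when the subgraph has no edges.
#'
#' @param metanet a `metanetwork`.
#' @param table the [count_table] presence is read from (rarefied counts;
#'   must contain `sample_id`).
#' @param sample_id sample to evaluate.
#' @param sign `"+"` (co-occurrence) or `"-"` (co-exclusion).
#' @param seed RNG seed for the Louvain restarts.
#' @param restarts Louvain restarts (default 10).
#' @return one-row data.frame: sample_id, marker, sign, n_nodes, n_edges,
#'   modularity, transitivity, average_path_length.
#' @export
local_properties <- function(metanet, table, sample_id, sign = c("+", "-"),
                             seed = 1L, restarts = 10) {
  sign <- match.arg(sign)
  m <- ct_counts(table)
  abort_if(!sample_id %in% rownames(m),
           sprintf("unknown sample '%s'", sample_id))
  present <- colnames(m)[m[sample_id, ] > 0]
  nodes <- intersect(metanet$taxa, present)
  e <- metanet$edges
  e <- e[e$sign == sign & e$node_a %in% nodes & e$node_b %in% nodes, ,
         drop = FALSE]
  g <- edges_to_igraph(e, nodes = nodes)
  gp <- graph_props(g, seed = seed, restarts = restarts)
  data.frame(sample_id = sample_id, marker = metanet$marker, sign = sign,
             n_nodes = length(nodes), n_edges = gp$n_edges,
             modularity = gp$modularity, transitivity = gp$transitivity,
             average_path_length = gp$average_path_length,
             stringsAsFactors = FALSE)
}

#' Local network properties for every sample x marker x sign
#'
#' Convenience wrapper over [local_properties()]: one row per sample,
#' marker and edge sign (co-occurrence and co-exclusion), with missing
#' values propagated where a subgraph has no edges. Together with alpha
#' diversity these per-sample values are the microbiome indexes fed into
#' the association network.
#'
#' @param metanets named list of `metanetwork` objects keyed by marker.
#' @param tables named list of rarefied [count_table]s keyed by marker.
#' @param seed RNG seed.
#' @param restarts Louvain restarts per subgraph.
#' @return data.frame with one row per sample x marker x sign.
#' @export
local_properties_all <- function(metanets, tables, seed = 1L,
                                 restarts = 10) {
  rows <- list()
  for (marker in names(metanets)) {
    tab <- tables[[marker]]
    abort_if(is.null(tab), sprintf("no table for marker '%s'", marker))
    for (s in ct_samples(tab)) {
      for (sg in c("+", "-")) {
        rows[[length(rows) + 1L]] <-
          local_properties(metanets[[marker]], tab, s, sign = sg,
                           seed = derive_seed(seed, paste(marker, s, sg)),
                           restarts = restarts)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spread local properties to one column per index
#'
#' Reshapes [local_properties_all()] output into a wide per-sample table
#' with columns like `16S_cooccur_transitivity`, the "microbiome index"
#' layout used by the association network.
#'
#' @param props long data.frame from [local_properties_all()].
#' @return wide data.frame keyed by sample_id.
#' @export
local_properties_wide <- function(props) {
  props$signlab <- ifelse(props$sign == "+", "cooccur", "coexclude")
  out <- data.frame(sample_id = unique(props$sample_id),
                    stringsAsFactors = FALSE)
  for (marker in unique(props$marker)) {
    for (sg in unique(props$signlab)) {
      sub <- props[props$marker == marker & props$signlab == sg, ]
      idx <- match(out$sample_id, sub$sample_id)
      for (v in c("modularity", "transitivity", "average_path_length")) {
        out[[paste(marker, sg, v, sep = "_")]] <- sub[[v]][idx]
      }
    }
  }
  out
}
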