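# Brute-force graph oracles, written directly from the definitions and
# independent of igraph. All take a 0/1 adjacency matrix.

oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(adj[v, ] == 1)) {
        if (is.infinite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
      }
    }
    frontier <- unique(nxt)
  }
  d
}

oracle_transitivity <- function(adj) {
  tri <- sum(diag(adj %*% adj %*% adj)) / 6
  deg <- rowSums(adj)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(0)
  3 * tri / triples
}

# mean shortest-path distance over connected pairs; NA when no edges
oracle_apl <- function(adj) {
  n <- nrow(adj)
  if (sum(adj) == 0) return(NA_real_)
  ds <- c()
  for (s in seq_len(n - 1)) {
    d <- oracle_bfs_dist(adj, s)
    dd <- d[(s + 1):n]
    ds <- c(ds, dd[is.finite(dd) & dd > 0])
  }
  if (length(ds) == 0) NA_real_ else mean(ds)
}

# exact betweenness by shortest-path counting over all pairs
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  if (n < 3) return(btw)
  # sigma[s, v]: number of shortest s->v paths
  dist <- t(vapply(seq_len(n), function(s) oracle_bfs_dist(adj, s),
                   numeric(n)))
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(dist[s, ])
    for (v in ord) {
      if (v == s || is.infinite(dist[s, v])) next
      preds <- which(adj[v, ] == 1 & dist[s, ] == dist[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(dist[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw
}

# exhaustive maximum modularity over all vertex partitions
oracle_max_modularity <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  deg <- rowSums(adj)
  best <- -Inf
  part <- integer(n)
  recurse <- function(i, kmax) {
    if (i > n) {
      q <- 0
      for (c in seq_len(kmax)) {
        w <- part == c
        lc <- sum(adj[w, w, drop = FALSE]) / 2
        dc <- sum(deg[w])
        q <- q + lc / m - (dc / (2 * m))^2
      }
      if (q > best) best <<- q
      return(invisible())
    }
    for (c in seq_len(kmax + 1)) {  # restricted growth: no relabel dups
      part[i] <<- c
      recurse(i + 1, max(kmax, c))
    }
  }
  recurse(1L, 0L)
  best
}

oracle_modularity_of <- function(adj, part) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(part)) {
    w <- part == c
    q <- q + sum(adj[w, w, drop = FALSE]) / 2 / m -
      (sum(deg[w]) / (2 * m))^2
  }
  q
}

adj_is_connected <- function(adj) {
  all(is.finite(oracle_bfs_dist(adj, 1)))
}

# all labelled connected graphs on n nodes (n <= 5 is practical)
enumerate_connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  np <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^np) - 1L) {
    adj <- matrix(0, n, n)
    bits <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    if (length(bits) < n - 1) next  # connectivity needs >= n-1 edges
    for (b in bits) adj[pairs[b, 1], pairs[b, 2]] <-
        adj[pairs[b, 2], pairs[b, 1]] <- 1
    if (adj_is_connected(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

random_connected_adj <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0, n, n)
    up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1, p)
    adj <- adj + t(adj)
    if (adj_is_connected(adj) && sum(adj) > 0) return(adj)
  }
}

adj_to_igraph <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("v", seq_len(nrow(adj)))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

adj_to_edges <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("v", seq_len(nrow(adj)))
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  data.frame(node_a = rownames(adj)[idx[, 1]],
             node_b = colnames(adj)[idx[, 2]],
             sign = "+", weight = 1, p = 0.01, q = 0.01,
             stringsAsFactors = FALSE)
}
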