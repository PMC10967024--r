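#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` are dropped and reported in the `"dropped"` attribute.
#' Deterministic under `seed`.
#'
#' @param table a [count_table].
#' @param depth target depth (>= 1).
#' @param seed RNG seed.
#' @return a rarefied [count_table]; attribute `dropped` lists removed
#'   sample ids.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  abort_if(depth < 1, "depth must be >= 1")
  m <- ct_counts(table)
  tot <- rowSums(m)
  keep <- tot >= depth
  abort_if(!any(keep), "all samples below depth")
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(m, 1, subsample_counts, depth = depth))
  })
  dimnames(out) <- dimnames(m)
  res <- count_table(out, table$marker)
  attr(res, "dropped") <- dropped
  res
}

# Draw `depth` reads without replacement from one sample's count vector.
subsample_counts <- function(x, depth) {
  tot <- sum(x)
  if (tot == depth) return(x)
  reads <- rep.int(seq_along(x), x)
  picked <- sample(reads, depth, replace = FALSE)
  tabulate(picked, nbins = length(x))
}

#' Rarefaction curves
#'
#' Mean observed richness and Shannon index per sample across repeated
#' random subsamples at each depth. Samples below a depth get `NA` there.
#'
#' @param table a [count_table].
#' @param depths increasing vector of depths.
#' @param n_draws random subsamples averaged per depth (default 10).
#' @param seed RNG seed.
#' @return long data.frame: sample_id, depth, richness, shannon.
#' @export
rarefaction_curve <- function(table, depths, n_draws = 10, seed = 1L) {
  abort_if(is.unsorted(depths, strictly = TRUE), "depths must be increasing")
  m <- ct_counts(table)
  with_seed(seed, {
    rows <- list()
    for (d in depths) {
      for (s in rownames(m)) {
        x <- m[s, ]
        if (sum(x) < d) {
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = s, depth = d, richness = NA_real_,
                       shannon = NA_real_)
          next
        }
        rich <- sh <- numeric(n_draws)
        for (i in seq_len(n_draws)) {
          sub <- subsample_counts(x, d)
          rich[i] <- sum(sub > 0)
          p <- sub[sub > 0] / d
          sh[i] <- -sum(p * log(p))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = s, depth = d, richness = mean(rich),
                     shannon = mean(sh))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Alpha diversity: observed richness, Shannon, bias-corrected Chao1
#'
#' Shannon is `-sum p_i log p_i` over taxa with nonzero counts (natural
#' log). Chao1 is the bias-corrected estimator
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton/doubleton
#' counts. Empty samples yield `NA` for all indexes.
#'
#' @param table a [count_table].
#' @return data.frame: sample_id, observed, shannon, chao1.
#' @export
alpha_diversity <- function(table) {
  m <- ct_counts(table)
  out <- data.frame(sample_id = rownames(m),
                    observed = NA_real_, shannon = NA_real_,
                    chao1 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    tot <- sum(x)
    if (tot == 0) next
    s <- sum(x > 0)
    p <- x[x > 0] / tot
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    out$observed[i] <- s
    out$shannon[i] <- -sum(p * log(p))
    out$chao1[i] <- s + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis distance matrix
#'
#' Computed on relative abundances: `d(x, y) = sum |p_i - q_i| / 2` with
#' `p`, `q` the per-sample proportions, so the distance is invariant to
#' library size.
#'
#' @param table a [count_table] or a samples x taxa numeric matrix.
#' @return symmetric distance matrix with sample dimnames.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "count_table")) ct_counts(table) else table
  abort_if(nrow(m) < 2, "need at least 2 samples")
  tot <- rowSums(m)
  abort_if(any(tot == 0), "zero-total sample")
  p <- m / tot
  d <- as.matrix(stats::dist(p, method = "manhattan")) / 2
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2` followed
#' by eigendecomposition. Coordinates are returned for axes with positive
#' eigenvalues; negative eigenvalues are reported but excluded from the
#' variance fractions. No negative-eigenvalue correction is applied.
#'
#' @param d square symmetric distance matrix, zero diagonal.
#' @param tol asymmetry tolerance.
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, decreasing), `prop_explained` (positive axes).
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  abort_if(nrow(d) != ncol(d), "distance matrix must be square")
  abort_if(max(abs(d - t(d))) > tol, "asymmetric distance matrix")
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(abs(ev)) * 1e-10)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = ev,
                 prop_explained = ev[pos] / sum(ev[pos])),
            class = "pcoa_result")
}

# Build the sequential design matrices for a vector of term labels such as
# c("location", "time", "location:treatment"). Returns a list of column
# index sets into a combined full-rank model matrix.
term_designs <- function(frame, terms) {
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  df <- as.data.frame(frame)
  for (nm in c("location", "treatment", "timepoint")) {
    if (nm %in% names(df)) df[[nm]] <- factor(df[[nm]])
  }
  if ("time" %in% all.vars(fml) && !"time" %in% names(df)) {
    df$time <- factor(df$timepoint)
  }
  for (v in all.vars(fml)) {
    col <- df[[v]]
    abort_if(is.null(col), sprintf("unknown term variable '%s'", v))
    abort_if(length(unique(col[!is.na(col)])) < 2,
             sprintf("term '%s' has a single level", v))
  }
  mm <- stats::model.matrix(fml, df)
  asg <- attr(mm, "assign")
  labs <- attr(stats::terms(fml), "term.labels")
  list(mm = mm, assign = asg, labels = labs)
}

# Trace of H %*% G for a hat matrix defined by design columns X (with
# intercept already included), via QR.
hat_trace <- function(X, G) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  sum((t(Q) %*% G) * t(Q))
}

#' PERMANOVA with sequential (Type I) partitioning
#'
#' Permutational multivariate ANOVA on a distance matrix. Sums of squares
#' are partitioned sequentially in the listed term order (terms may
#' include interactions such as `"location:treatment"`); significance is
#' assessed by free permutation of sample labels, or within-location
#' strata when `strata = "location"`.
#' `p = (1 + #[F* >= F]) / (1 + n_perm)`.
#'
#' @param d distance matrix (samples match `frame$sample_id` order).
#' @param frame a [sample_frame].
#' @param terms character vector of term labels, evaluated in order.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param strata `NULL` (free permutation) or `"location"`.
#' @return data.frame of class `permanova_result`: term, df, SS, R2 (%),
#'   pseudo-F, p; last row is the residual.
#' @export
permanova <- function(d, frame, terms, n_perm = 999, seed = 1L,
                      strata = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  abort_if(n != nrow(frame), "distance matrix and frame size differ")
  td <- term_designs(frame, terms)
  a <- -0.5 * d^2
  G <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  ss_total <- sum(diag(G))

  stat_fun <- function(Gp) {
    tr_prev <- hat_trace(matrix(1, n, 1), Gp)  # intercept only: 0
    ss <- df <- numeric(length(td$labels))
    rank_prev <- 1L
    for (k in seq_along(td$labels)) {
      X <- td$mm[, td$assign <= k, drop = FALSE]
      qk <- qr(X)
      tr_k <- hat_trace(X, Gp)
      ss[k] <- tr_k - tr_prev
      df[k] <- qk$rank - rank_prev
      tr_prev <- tr_k; rank_prev <- qk$rank
    }
    ss_res <- sum(diag(Gp)) - tr_prev
    df_res <- n - rank_prev
    f <- (ss / df) / (ss_res / df_res)
    list(ss = ss, df = df, f = f, ss_res = ss_res, df_res = df_res)
  }

  obs <- stat_fun(G)
  exceed <- rep(0L, length(td$labels))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- permute_indices(n, frame, strata)
      st <- stat_fun(G[idx, idx])
      exceed <- exceed + as.integer(st$f >= obs$f)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(term = c(td$labels, "Residual"),
                    df = c(obs$df, obs$df_res),
                    SS = c(obs$ss, obs$ss_res),
                    R2 = 100 * c(obs$ss, obs$ss_res) / ss_total,
                    pseudo_F = c(obs$f, NA_real_),
                    p = c(p, NA_real_), stringsAsFactors = FALSE)
  class(out) <- c("permanova_result", class(out))
  out
}

permute_indices <- function(n, frame, strata) {
  if (is.null(strata)) return(sample.int(n))
  g <- frame[[strata]]
  idx <- seq_len(n)
  for (lev in unique(g)) {
    w <- which(g == lev)
    idx[w] <- w[sample.int(length(w))]
  }
  idx
}

#' Fit environmental vectors to an ordination
#'
#' For each numeric variable, `R2` is the squared multiple correlation of
#' the variable with the first two ordination axes (complete cases only);
#' `p` is obtained by permuting the variable's values.
#'
#' @param ordination a `pcoa_result` (or matrix of coordinates).
#' @param frame a [sample_frame] aligned with the ordination rows.
#' @param variables character vector of numeric variable names.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame: variable, R2, p, n_used.
#' @export
fit_vectors <- function(ordination, frame, variables, n_perm = 999,
                        seed = 1L) {
  coords <- if (inherits(ordination, "pcoa_result")) {
    ordination$coordinates
  } else as.matrix(ordination)
  k <- min(2L, ncol(coords))
  coords <- coords[, seq_len(k), drop = FALSE]
  out <- data.frame(variable = variables, R2 = NA_real_, p = NA_real_,
                    n_used = NA_integer_, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (i in seq_along(variables)) {
      v <- frame[[variables[i]]]
      abort_if(is.null(v), sprintf("unknown variable '%s'", variables[i]))
      ok <- !is.na(v)
      abort_if(sum(ok) < 3, "need >= 3 complete samples")
      vv <- v[ok]; cc <- coords[ok, , drop = FALSE]
      abort_if(stats::sd(vv) == 0,
               sprintf("constant variable '%s'", variables[i]))
      r2 <- summary(stats::lm(vv ~ cc))$r.squared
      ex <- 0L
      for (b in seq_len(n_perm)) {
        r2p <- summary(stats::lm(sample(vv) ~ cc))$r.squared
        if (r2p >= r2) ex <- ex + 1L
      }
      out$R2[i] <- r2
      out$p[i] <- (1 + ex) / (1 + n_perm)
      out$n_used[i] <- sum(ok)
    }
  })
  out
}

#' Location-centered redundancy analysis on log counts
#'
#' The community matrix is `log(1 + count)`, centered by subtracting each
#' location's mean taxon profile (removing the location effect), then fit
#' by least squares on the sequential term design (treatment, time and/or
#' numeric covariates). Per-term variance explained is the sequential
#' share of the total sum of squares; significance comes from permuting
#' residuals under the reduced model (the model with all preceding
#' terms). Residual rows are permuted within location strata: location
#' centering constrains each location block to sum to zero, so rows are
#' exchangeable only within a location, and free permutation would make
#' the test anticonservative (see the methods vignette).
#'
#' @param table a [count_table] (typically rarefied).
#' @param frame a [sample_frame] covering the table's samples.
#' @param terms character vector from {treatment, time, numeric covariate
#'   names}.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame of class `rda_result`: term, df, SS, R2 (%),
#'   pseudo-F, p; last row is the residual.
#' @export
rda_location_centered <- function(table, frame, terms, n_perm = 999,
                                  seed = 1L) {
  m <- ct_counts(table)
  fr <- as.data.frame(frame)
  fr <- fr[match(rownames(m), fr$sample_id), , drop = FALSE]
  abort_if(any(is.na(fr$sample_id)), "frame does not cover all samples")
  Y <- log1p(m)
  for (lev in unique(fr$location)) {
    w <- fr$location == lev
    Y[w, ] <- sweep(Y[w, , drop = FALSE], 2,
                    colMeans(Y[w, , drop = FALSE]))
  }
  n <- nrow(Y)
  td <- term_designs(fr, terms)
  qr_full <- qr(td$mm)
  abort_if(qr_full$rank < ncol(td$mm), "singular design")
  ss_total <- sum(Y^2)

  proj_fit <- function(X, Ym) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    Q %*% (t(Q) %*% Ym)
  }

  nt <- length(td$labels)
  ss <- df <- fstat <- pval <- numeric(nt)
  fit_prev <- proj_fit(matrix(1, n, 1), Y)
  ss_prev <- sum(fit_prev^2)
  rank_prev <- 1L
  fit_full <- proj_fit(td$mm, Y)
  ss_res_full <- sum((Y - fit_full)^2)
  df_res_full <- n - qr_full$rank

  with_seed(seed, {
    for (k in seq_len(nt)) {
      Xk <- td$mm[, td$assign <= k, drop = FALSE]
      qk <- qr(Xk)
      fit_k <- proj_fit(Xk, Y)
      ss_k <- sum(fit_k^2)
      ss[k] <- ss_k - ss_prev
      df[k] <- qk$rank - rank_prev
      fstat[k] <- (ss[k] / df[k]) / (ss_res_full / df_res_full)
      # residual permutation under the reduced model (terms < k)
      Xred <- td$mm[, td$assign < k, drop = FALSE]
      fit_red <- proj_fit(Xred, Y)
      res_red <- Y - fit_red
      ex <- 0L
      for (b in seq_len(n_perm)) {
        idx <- permute_indices(n, fr, "location")
        Yp <- fit_red + res_red[idx, , drop = FALSE]
        f_kp <- sum(proj_fit(Xk, Yp)^2) - sum(proj_fit(Xred, Yp)^2)
        res_p <- sum(Yp^2) - sum(proj_fit(td$mm, Yp)^2)
        fp <- (f_kp / df[k]) / (res_p / df_res_full)
        if (fp >= fstat[k]) ex <- ex + 1L
      }
      pval[k] <- (1 + ex) / (1 + n_perm)
      ss_prev <- ss_k; rank_prev <- qk$rank
    }
  })
  out <- data.frame(term = c(td$labels, "Residual"),
                    df = c(df, df_res_full),
                    SS = c(ss, ss_res_full),
                    R2 = 100 * c(ss, ss_res_full) / ss_total,
                    pseudo_F = c(fstat, NA_real_),
                    p = c(pval, NA_real_), stringsAsFactors = FALSE)
  class(out) <- c("rda_result", class(out))
  out
}
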