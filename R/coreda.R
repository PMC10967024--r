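#' Core-microbiome prevalence profile
#'
#' For each condition group (e.g. control-T0, treated-T1), the fraction
#' of samples in which each taxon exceeds each relative-abundance
#' detection threshold. Core membership: prevalence >= `core_prevalence`
#' at `core_detection` AND detected in every location (at the same
#' detection level).
#'
#' @param table a [count_table].
#' @param frame a [sample_frame] covering the table's samples.
#' @param detections detection thresholds on relative abundance, each in
#'   (0, 1).
#' @param group_by metadata columns defining groups (default
#'   `c("treatment", "timepoint")`).
#' @param core_detection detection level for the core rule (default 0.01).
#' @param core_prevalence prevalence threshold for the core rule
#'   (default 0.25).
#' @return list of class `core_profile`: `prevalence` (named list of taxa
#'   x detections matrices per group), `core` (named list of logical
#'   vectors per group), `detections`, `groups`.
#' @export
prevalence_profile <- function(table, frame,
                               detections = c(0.001, 0.01, 0.05),
                               group_by = c("treatment", "timepoint"),
                               core_detection = 0.01,
                               core_prevalence = 0.25) {
  abort_if(any(detections <= 0 | detections >= 1),
           "detections must be in (0, 1)")
  m <- ct_counts(table)
  fr <- as.data.frame(frame)
  fr <- fr[match(rownames(m), fr$sample_id), , drop = FALSE]
  rel <- m / rowSums(m)
  grp <- interaction(fr[group_by], drop = TRUE, sep = "-")
  prev <- list(); core <- list()
  for (g in levels(grp)) {
    w <- grp == g
    abort_if(!any(w), sprintf("empty group '%s'", g))
    sub <- rel[w, , drop = FALSE]
    pm <- vapply(detections, function(d) colMeans(sub > d),
                 numeric(ncol(sub)))
    colnames(pm) <- as.character(detections)
    prev[[g]] <- pm
    pcore <- colMeans(sub > core_detection) >= core_prevalence
    # all-locations rule: detected in >= 1 sample of every location
    locs <- unique(fr$location[w])
    in_all <- rep(TRUE, ncol(sub))
    for (l in locs) {
      wl <- w & fr$location == l
      in_all <- in_all & colSums(rel[wl, , drop = FALSE] > core_detection) > 0
    }
    core[[g]] <- stats::setNames(pcore & in_all, colnames(sub))
  }
  structure(list(prevalence = prev, core = core, detections = detections,
                 groups = levels(grp)), class = "core_profile")
}

#' Shared and exclusive taxa, constrained by location
#'
#' Counts taxa shared between control and treated arms at each timepoint.
#' Under the location constraint a taxon counts as shared only if it is
#' co-detected (count > 0) in control and treated samples of at least one
#' common location; the unconstrained mode uses plain set intersection of
#' detected taxa.
#'
#' @param table a [count_table] (ASV or genus level).
#' @param frame a [sample_frame].
#' @param constrained apply the common-location rule (default TRUE).
#' @return data.frame: timepoint, shared, control_only, treated_only,
#'   with attribute `members` (named list of shared-taxon id vectors).
#' @export
shared_taxa_constrained <- function(table, frame, constrained = TRUE) {
  m <- ct_counts(table)
  fr <- as.data.frame(frame)
  fr <- fr[match(rownames(m), fr$sample_id), , drop = FALSE]
  out <- list(); members <- list()
  for (tp in sort(unique(fr$timepoint))) {
    wc <- fr$timepoint == tp & fr$treatment == "control"
    wt <- fr$timepoint == tp & fr$treatment == "treated"
    abort_if(!any(wc) || !any(wt),
             sprintf("missing arm at timepoint %s", tp))
    det_c <- colSums(m[wc, , drop = FALSE] > 0) > 0
    det_t <- colSums(m[wt, , drop = FALSE] > 0) > 0
    if (constrained) {
      shared <- rep(FALSE, ncol(m))
      for (l in intersect(unique(fr$location[wc]), unique(fr$location[wt]))) {
        cl <- colSums(m[wc & fr$location == l, , drop = FALSE] > 0) > 0
        tl <- colSums(m[wt & fr$location == l, , drop = FALSE] > 0) > 0
        shared <- shared | (cl & tl)
      }
    } else {
      shared <- det_c & det_t
    }
    out[[tp]] <- data.frame(timepoint = tp, shared = sum(shared),
                            control_only = sum(det_c & !shared),
                            treated_only = sum(det_t & !shared),
                            stringsAsFactors = FALSE)
    members[[tp]] <- colnames(m)[shared]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "members") <- members
  res
}

# Median-of-ratios size factors over taxa with all-positive counts;
# library-size fallback (normalized to geometric mean 1) when no taxon is
# positive everywhere.
size_factors <- function(m) {
  allpos <- colSums(m == 0) == 0
  if (any(allpos)) {
    lg <- log(m[, allpos, drop = FALSE])
    ref <- colMeans(lg)  # log geometric mean per taxon
    sf <- apply(lg, 1, function(r) exp(stats::median(r - ref)))
  } else {
    ls <- rowSums(m)
    sf <- ls / exp(mean(log(ls)))
  }
  sf
}

#' Negative-binomial differential abundance (treated vs control)
#'
#' Per-taxon NB regression `count ~ treatment` with a log size-factor
#' offset (median-of-ratios size factors, library-size fallback).
#' Dispersion by per-taxon maximum likelihood ([MASS::glm.nb()]) with a
#' method-of-moments fallback when ML fails; Wald test on the treatment
#' coefficient; BH correction across tested taxa. No shrinkage of
#' dispersions or fold changes is applied.
#'
#' @param table a [count_table] (any taxonomic level; aggregate first for
#'   genus-level tests).
#' @param frame a [sample_frame]; only rows matching the table's samples
#'   are used.
#' @param min_count_filter minimum taxon total across tested samples
#'   (default 10).
#' @param zero_arm_policy `"flag"` (default: taxa all-zero in one arm are
#'   reported untestable) or `"pseudo"` (add 0.5 to every count of such a
#'   taxon, a documented continuity correction).
#' @return data.frame of class `da_result`: taxon, baseMean, log2FC, SE,
#'   wald, p, q, status ("ok", "low_count", "zero_arm", "fit_failed"),
#'   dispersion.
#' @export
nb_differential_abundance <- function(table, frame, min_count_filter = 10,
                                      zero_arm_policy = c("flag", "pseudo")) {
  zero_arm_policy <- match.arg(zero_arm_policy)
  m <- ct_counts(table)
  fr <- as.data.frame(frame)
  fr <- fr[match(rownames(m), fr$sample_id), , drop = FALSE]
  treat <- factor(fr$treatment, levels = c("control", "treated"))
  abort_if(min(table(treat)) < 3, "need >= 3 samples per arm")
  sf <- size_factors(m)
  off <- log(sf)
  taxa <- colnames(m)
  out <- data.frame(taxon = taxa, baseMean = NA_real_, log2FC = NA_real_,
                    SE = NA_real_, wald = NA_real_, p = NA_real_,
                    q = NA_real_, status = "ok", dispersion = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(taxa)) {
    y <- m[, i]
    out$baseMean[i] <- mean(y / sf)
    if (sum(y) < min_count_filter) { out$status[i] <- "low_count"; next }
    zero_arm <- any(tapply(y, treat, function(v) all(v == 0)))
    if (zero_arm) {
      if (zero_arm_policy == "flag") { out$status[i] <- "zero_arm"; next }
      y <- y + 0.5
    }
    fit <- fit_nb_wald(y, treat, off)
    if (is.null(fit)) { out$status[i] <- "fit_failed"; next }
    out$log2FC[i] <- fit$beta / log(2)
    out$SE[i] <- fit$se / log(2)
    out$wald[i] <- fit$beta / fit$se
    out$p[i] <- 2 * stats::pnorm(-abs(out$wald[i]))
    out$dispersion[i] <- fit$dispersion
  }
  tested <- out$status == "ok" & !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  class(out) <- c("da_result", class(out))
  out
}

# One-taxon NB Wald fit: ML dispersion via glm.nb, method-of-moments
# fallback with a dispersion floor; returns treatment coefficient (natural
# log scale), its SE and the dispersion alpha = 1/theta.
fit_nb_wald <- function(y, treat, off) {
  df <- data.frame(y = y, treat = treat, off = off)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ treat + offset(off), data = df,
                                  control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    # method-of-moments dispersion on normalized counts, pooled over arms
    z <- y / exp(off)
    alpha <- 0
    for (lev in levels(treat)) {
      v <- z[treat == lev]
      mu <- mean(v)
      if (mu > 0) alpha <- max(alpha, (stats::var(v) - mu) / mu^2)
    }
    alpha <- max(alpha, 1e-8)
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        y ~ treat + offset(off), data = df,
        family = MASS::negative.binomial(theta = 1 / alpha))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- summary(fit)$coefficients
    return(list(beta = cf["treattreated", "Estimate"],
                se = cf["treattreated", "Std. Error"],
                dispersion = alpha))
  }
  cf <- summary(fit)$coefficients
  list(beta = cf["treattreated", "Estimate"],
       se = cf["treattreated", "Std. Error"],
       dispersion = 1 / fit$theta)
}
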