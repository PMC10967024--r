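#' Trial design for the synthetic multi-location generator
#'
#' Describes the factorial layout of a two-arm biostimulant field trial:
#' locations x {control, treated} x replicate sub-plots x {T0, T1}
#' timepoints, with one amplicon count table per marker. Defaults mirror a
#' 21-location trial with three replicated sub-plots per arm and two soil
#' sampling timepoints (before planting and ~30 days after emergence).
#'
#' @param n_locations number of locations (>= 2).
#' @param n_replicates_per_arm replicate sub-plots per treatment arm per
#'   location (>= 2; default 3).
#' @param timepoints timepoint labels, fixed at `c("T0","T1")`.
#' @param markers markers to simulate (subset of `c("16S","ITS")`; may be
#'   empty to generate metadata only, e.g. for yield-only simulations).
#' @param n_taxa_per_marker named count of taxa per marker.
#' @param library_size_range inclusive integer range library sizes are
#'   drawn from, uniformly; must stay at or above the rarefaction depth
#'   used downstream.
#' @param seed RNG seed; every random draw in [generate_trial()] flows
#'   from it.
#' @return a `trial_design` list.
#' @export
trial_design <- function(n_locations = 21,
                         n_replicates_per_arm = 3,
                         timepoints = c("T0", "T1"),
                         markers = c("16S", "ITS"),
                         n_taxa_per_marker = c("16S" = 150, "ITS" = 150),
                         library_size_range = c(20000, 35000),
                         seed = 1L) {
  abort_if(n_locations < 2, "n_locations must be >= 2")
  abort_if(n_replicates_per_arm < 2, "n_replicates_per_arm must be >= 2")
  abort_if(!identical(sort(timepoints), c("T0", "T1")),
           "timepoints must be T0 and T1")
  abort_if(length(markers) > 0 && !all(markers %in% c("16S", "ITS")),
           "markers must be among 16S, ITS")
  abort_if(length(markers) > 0 &&
             !all(markers %in% names(n_taxa_per_marker)),
           "n_taxa_per_marker must name every marker")
  abort_if(any(library_size_range < 1), "library size below 1")
  abort_if(length(markers) > 0 && any(n_taxa_per_marker[markers] < 1),
           "empty taxon set")
  structure(list(n_locations = as.integer(n_locations),
                 n_replicates_per_arm = as.integer(n_replicates_per_arm),
                 timepoints = c("T0", "T1"),
                 markers = markers,
                 n_taxa_per_marker = n_taxa_per_marker,
                 library_size_range = as.integer(library_size_range),
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' Planted effects for the synthetic generator
#'
#' The knobs that give the synthetic trial its recoverable structure:
#'
#' * `location_concentration` — Dirichlet concentration of per-location
#'   mean compositions around a global log-normal taxon profile; smaller
#'   values give stronger between-location divergence (`Inf` = no location
#'   effect). The default (25) makes location the dominant source of
#'   compositional variance, with within-location Dirichlet concentration
#'   `sample_concentration` (200) keeping replicates similar.
#' * `treated_lfc` / `n_treated_taxa` / `treated_marker` — a multiplicative
#'   abundance shift (log fold change) applied to the most abundant
#'   non-pair taxa of one marker in treated T1 samples only; the default
#'   plants a 4-fold shift on 20 fungal (ITS) taxa, emulating a
#'   treatment effect concentrated in the fungal community.
#' * `n_cooccur_pairs` / `n_coexclude_pairs` / `pair_coupling` — taxon
#'   pairs whose presence is driven by a shared Bernoulli latent factor
#'   (co-occurring members follow the same factor, co-excluding members
#'   opposite factors) with probability `pair_coupling`, else an
#'   independent coin; present members get a boosted compositional weight,
#'   absent members exactly zero.
#' * `yield_model` — coefficients linking yield (T1 rows only) to
#'   treatment (`treatment_pct`, default +15% of the location base), a
#'   designated network-structure proxy covariate (`proxy`, coefficient
#'   `proxy_coef`) and named metadata covariates (`covariate_coefs`);
#'   `noise_sd` is the Gaussian yield noise (cwt/ac scale).
#'
#' @param location_concentration positive real or `Inf`.
#' @param sample_concentration positive real; within-location Dirichlet
#'   concentration.
#' @param treated_marker marker carrying the treatment shift (or `NULL`).
#' @param n_treated_taxa number of treated taxa.
#' @param treated_lfc natural-log fold change applied in treated-T1 cells.
#' @param n_cooccur_pairs,n_coexclude_pairs planted pair counts per marker.
#' @param pair_coupling probability a pair member follows the shared
#'   latent factor.
#' @param pair_presence_prob Bernoulli rate of the latent factor.
#' @param pair_boost present-member compositional weight as a multiple of
#'   the mean taxon weight.
#' @param yield_model list with `base`, `location_sd`, `treatment_pct`,
#'   `proxy`, `proxy_coef`, `covariate_coefs`.
#' @param noise_sd Gaussian yield noise sd.
#' @return a `planted_effects` list.
#' @export
planted_effects <- function(location_concentration = 25,
                            sample_concentration = 200,
                            treated_marker = "ITS",
                            n_treated_taxa = 20,
                            treated_lfc = log(4),
                            n_cooccur_pairs = 5,
                            n_coexclude_pairs = 5,
                            pair_coupling = 0.9,
                            pair_presence_prob = 0.5,
                            pair_boost = 5,
                            yield_model = list(base = 400,
                                               location_sd = 60,
                                               treatment_pct = 0.15,
                                               proxy = "connectivity",
                                               proxy_coef = 30,
                                               covariate_coefs =
                                                 c(soil_ca = 0.1)),
                            noise_sd = 30) {
  abort_if(location_concentration <= 0, "location_concentration must be > 0")
  abort_if(noise_sd <= 0, "noise_sd must be positive")
  abort_if(n_treated_taxa > 0 && !is.null(treated_marker) &&
             (!is.finite(treated_lfc) || treated_lfc == 0),
           "fold changes must be finite and nonzero for treated taxa")
  abort_if(pair_coupling < 0 || pair_coupling > 1,
           "pair_coupling must be in [0,1]")
  structure(list(location_concentration = location_concentration,
                 sample_concentration = sample_concentration,
                 treated_marker = treated_marker,
                 n_treated_taxa = as.integer(n_treated_taxa),
                 treated_lfc = treated_lfc,
                 n_cooccur_pairs = as.integer(n_cooccur_pairs),
                 n_coexclude_pairs = as.integer(n_coexclude_pairs),
                 pair_coupling = pair_coupling,
                 pair_presence_prob = pair_presence_prob,
                 pair_boost = pair_boost,
                 yield_model = yield_model,
                 noise_sd = noise_sd),
            class = "planted_effects")
}

#' Null planted effects
#'
#' Convenience constructor: no location structure, no treatment effect,
#' no planted pairs, no yield dependence on treatment or proxy. Used for
#' type-I-error simulations.
#'
#' @param ... overrides forwarded to [planted_effects()].
#' @export
null_effects <- function(...) {
  args <- list(location_concentration = Inf,
               treated_marker = NULL, n_treated_taxa = 0L,
               n_cooccur_pairs = 0L, n_coexclude_pairs = 0L,
               yield_model = list(base = 400, location_sd = 0,
                                  treatment_pct = 0, proxy = "connectivity",
                                  proxy_coef = 0, covariate_coefs = numeric(0)))
  utils::modifyList(do.call(planted_effects, args), list(...))
}

# Environmental / nutrient covariates emulated by the generator:
# location-specific means, plot-level Gaussian noise. petiole and yield
# exist only at T1 (harvest-side measurements); soil and environment at
# both timepoints.
covariate_spec <- function() {
  data.frame(
    name = c("soil_ca", "soil_k", "soil_mn", "soil_ph", "petiole_n",
             "ndvi_m04", "soil_temp_wetq", "connectivity"),
    mean = c(1500, 250, 12, 6.5, 4.2, 0.45, 16, 0),
    between_sd = c(350, 60, 4, 0.5, 0.6, 0.1, 3, 0.5),
    within_sd = c(80, 20, 1.5, 0.15, 0.35, 0.03, 0.8, 1),
    t1_only = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-location trial
#'
#' Draws, under a single seeded generator, one count table per marker
#' (per-sample multinomial counts over a Dirichlet-perturbed
#' location-specific composition), a sample metadata frame with
#' location/treatment/timepoint design, nutrient and environmental
#' covariates with location-specific means, yield on T1 rows only, and a
#' truth record listing the planted pairs, treated taxa and yield
#' coefficients. A simple taxonomy table per marker is generated alongside
#' so genus-level stages are exercisable.
#'
#' @param design a [trial_design()].
#' @param effects a [planted_effects()].
#' @return list with elements `counts` (named list of [count_table]),
#'   `taxonomy` (named list of [taxonomy_table]), `frame`
#'   (a [sample_frame]) and `truth` (named list, see [write_truth()]).
#' @export
generate_trial <- function(design, effects = planted_effects()) {
  stopifnot(inherits(design, "trial_design"),
            inherits(effects, "planted_effects"))
  with_seed(design$seed, generate_trial_impl(design, effects))
}

generate_trial_impl <- function(design, effects) {
  nl <- design$n_locations; nr <- design$n_replicates_per_arm
  locs <- sprintf("L%02d", seq_len(nl))
  arms <- c("control", "treated")
  grid <- expand.grid(timepoint = design$timepoints,
                      replicate = seq_len(nr), treatment = arms,
                      location = locs, stringsAsFactors = FALSE)
  grid <- grid[, c("location", "treatment", "replicate", "timepoint")]
  grid$plot <- sprintf("%s_%s_r%d", grid$location, grid$treatment,
                       grid$replicate)
  grid$sample_id <- sprintf("%s_%s", grid$plot, grid$timepoint)

  # covariates: location means then plot-level values (shared by T0/T1 rows
  # of a plot for plot-constant quantities like connectivity)
  cs <- covariate_spec()
  cov_mat <- matrix(NA_real_, nrow(grid), nrow(cs),
                    dimnames = list(grid$sample_id, cs$name))
  loc_idx <- match(grid$location, locs)
  for (j in seq_len(nrow(cs))) {
    mu_loc <- stats::rnorm(nl, cs$mean[j], cs$between_sd[j])
    plot_ids <- unique(grid$plot)
    mu_plot <- mu_loc[match(sub("_(control|treated)_r\\d+$", "",
                                plot_ids), locs)] +
      stats::rnorm(length(plot_ids), 0, cs$within_sd[j])
    v <- mu_plot[match(grid$plot, plot_ids)]
    if (cs$t1_only[j]) v[grid$timepoint != "T1"] <- NA_real_
    cov_mat[, j] <- v
  }

  # yield at T1 rows only
  ym <- effects$yield_model
  loc_base <- ym$base + stats::rnorm(nl, 0, ym$location_sd %||% 0)
  yield <- rep(NA_real_, nrow(grid))
  t1 <- grid$timepoint == "T1"
  treat_num <- as.numeric(grid$treatment == "treated")
  lin <- loc_base[loc_idx] * (1 + (ym$treatment_pct %||% 0) * treat_num)
  cc <- ym$covariate_coefs %||% numeric(0)
  for (nm in names(cc)) {
    contrib <- cc[[nm]] * (cov_mat[, nm] - mean(cov_mat[, nm], na.rm = TRUE))
    contrib[is.na(contrib)] <- 0
    lin <- lin + contrib
  }
  if (!is.null(ym$proxy) && (ym$proxy_coef %||% 0) != 0) {
    lin <- lin + ym$proxy_coef * cov_mat[, ym$proxy]
  }
  yield[t1] <- lin[t1] + stats::rnorm(sum(t1), 0, effects$noise_sd)

  frame <- data.frame(sample_id = grid$sample_id, location = grid$location,
                      treatment = grid$treatment, timepoint = grid$timepoint,
                      plot = grid$plot, yield = yield,
                      as.data.frame(cov_mat), stringsAsFactors = FALSE,
                      check.names = FALSE)
  rownames(frame) <- NULL
  frame <- sample_frame(frame)

  truth <- list(seed = design$seed,
                n_locations = nl,
                pair_coupling = effects$pair_coupling,
                yield.treatment_pct = ym$treatment_pct %||% 0,
                yield.proxy = ym$proxy %||% "",
                yield.proxy_coef = ym$proxy_coef %||% 0)
  counts <- list(); taxonomy <- list()
  for (marker in design$markers) {
    gm <- generate_marker_counts(marker, design, effects, grid, treat_num)
    counts[[marker]] <- gm$table
    taxonomy[[marker]] <- gm$taxonomy
    truth[[paste0("treated_taxa.", marker)]] <- gm$treated_taxa
    truth[[paste0("treated_lfc.", marker)]] <-
      if (length(gm$treated_taxa)) effects$treated_lfc else 0
    if (length(gm$cooccur_pairs)) {
      truth[[paste0("cooccur_pairs.", marker)]] <-
        vapply(gm$cooccur_pairs, paste, character(1), collapse = "|")
    }
    if (length(gm$coexclude_pairs)) {
      truth[[paste0("coexclude_pairs.", marker)]] <-
        vapply(gm$coexclude_pairs, paste, character(1), collapse = "|")
    }
  }
  list(counts = counts, taxonomy = taxonomy, frame = frame, truth = truth)
}

generate_marker_counts <- function(marker, design, effects, grid, treat_num) {
  tcount <- as.integer(design$n_taxa_per_marker[[marker]])
  taxa <- sprintf("%s_tax%03d", marker, seq_len(tcount))
  ns <- nrow(grid)
  nl <- design$n_locations
  locs <- unique(grid$location)

  # global log-normal taxon-abundance profile
  g <- exp(stats::rnorm(tcount, 0, 1)); g <- g / sum(g)

  # reserve pair taxa at the tail of the index range
  nc <- effects$n_cooccur_pairs; nx <- effects$n_coexclude_pairs
  need <- 2L * (nc + nx)
  abort_if(need >= tcount, "too many planted pairs for the taxon count")
  pair_idx <- if (need > 0) seq(tcount - need + 1L, tcount) else integer(0)
  cooccur <- coexclude <- list()
  k <- 0L
  for (i in seq_len(nc)) {
    cooccur[[i]] <- taxa[pair_idx[k + 1:2]]; k <- k + 2L
  }
  for (i in seq_len(nx)) {
    coexclude[[i]] <- taxa[pair_idx[k + 1:2]]; k <- k + 2L
  }

  # treated taxa: the most globally abundant non-pair taxa of the treated
  # marker, so the planted shift is observable in most locations
  treated_taxa <- character(0)
  treat_idx <- integer(0)
  if (!is.null(effects$treated_marker) &&
      identical(marker, effects$treated_marker) &&
      effects$n_treated_taxa > 0) {
    free <- setdiff(seq_len(tcount), pair_idx)
    treat_idx <- free[order(g[free], decreasing = TRUE)][
      seq_len(min(effects$n_treated_taxa, length(free)))]
    treated_taxa <- taxa[treat_idx]
  }

  # per-location mean compositions: Dirichlet around the global profile,
  # total concentration = location_concentration (small => divergent)
  loc_p <- matrix(0, nl, tcount)
  for (l in seq_len(nl)) {
    loc_p[l, ] <- if (is.finite(effects$location_concentration)) {
      rdirichlet1(effects$location_concentration * g)
    } else g
  }

  lib_lo <- design$library_size_range[1]; lib_hi <- design$library_size_range[2]
  abort_if(lib_lo < 1, "library size below 1")
  libs <- sample(lib_lo:lib_hi, ns, replace = TRUE)

  pair_members <- c(unlist(cooccur), unlist(coexclude))
  pair_member_idx <- match(pair_members, taxa)
  base_pair_w <- effects$pair_boost / tcount

  counts <- matrix(0, ns, tcount, dimnames = list(grid$sample_id, taxa))
  loc_of <- match(grid$location, locs)
  is_t1 <- grid$timepoint == "T1"
  for (s in seq_len(ns)) {
    w <- loc_p[loc_of[s], ]
    if (length(treat_idx) && is_t1[s] && treat_num[s] == 1) {
      w[treat_idx] <- w[treat_idx] * exp(effects$treated_lfc)
    }
    if (length(pair_member_idx)) {
      pres <- pair_presence(effects, nc, nx)
      w[pair_member_idx] <- ifelse(pres, base_pair_w, 0)
    }
    w <- w / sum(w)
    x <- rdirichlet1(effects$sample_concentration * w)
    counts[s, ] <- stats::rmultinom(1, libs[s], x)
  }

  tax_df <- synth_taxonomy(marker, taxa)
  list(table = count_table(counts, marker),
       taxonomy = taxonomy_table(tax_df, marker),
       treated_taxa = treated_taxa,
       cooccur_pairs = cooccur, coexclude_pairs = coexclude)
}

# Presence vector for the planted-pair members of one sample, ordered as
# c(cooccur pairs' members, coexclude pairs' members).
pair_presence <- function(effects, nc, nx) {
  pres <- logical(0)
  for (i in seq_len(nc)) {
    z <- stats::rbinom(1, 1, effects$pair_presence_prob)
    m <- vapply(1:2, function(j) {
      if (stats::runif(1) < effects$pair_coupling) z
      else stats::rbinom(1, 1, effects$pair_presence_prob)
    }, numeric(1))
    pres <- c(pres, m == 1)
  }
  for (i in seq_len(nx)) {
    z <- stats::rbinom(1, 1, effects$pair_presence_prob)
    states <- c(z, 1 - z)
    m <- vapply(1:2, function(j) {
      if (stats::runif(1) < effects$pair_coupling) states[j]
      else stats::rbinom(1, 1, effects$pair_presence_prob)
    }, numeric(1))
    pres <- c(pres, m == 1)
  }
  pres
}

# Synthetic taxonomy: taxa grouped into genera (~2.5 taxa each on average),
# genera into a small pool of phyla/classes; ~5% of taxa unassigned at
# genus rank.
synth_taxonomy <- function(marker, taxa) {
  tcount <- length(taxa)
  kingdom <- if (marker == "ITS") "Fungi" else "Bacteria"
  phyla <- if (marker == "ITS") {
    c("Ascomycota", "Basidiomycota", "Mortierellomycota")
  } else {
    c("Proteobacteria", "Actinobacteriota", "Firmicutes",
      "Acidobacteriota", "Planctomycetota")
  }
  classes <- paste0(phyla, "_class")
  n_gen <- max(2L, round(tcount / 2.5))
  gen_pool <- sprintf("%s_gen%03d", marker, seq_len(n_gen))
  gen_phylum <- sample(phyla, n_gen, replace = TRUE)
  gidx <- sample(n_gen, tcount, replace = TRUE)
  genus <- gen_pool[gidx]
  phylum <- gen_phylum[gidx]
  unass <- stats::runif(tcount) < 0.05
  genus[unass] <- "unassigned"
  data.frame(taxon_id = taxa, kingdom = kingdom, phylum = phylum,
             class = classes[match(phylum, phyla)], genus = genus,
             stringsAsFactors = FALSE)
}
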