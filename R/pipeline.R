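#' Run configuration
#'
#' Plain-text `key=value` configuration mirroring the pipeline's knobs;
#' no hidden defaults outside this schema. Unknown keys are rejected.
#'
#' Keys (defaults in parentheses): `seed` (1), `out_dir` (required),
#' `synthetic` (true), `n_locations` (21), `n_replicates` (3),
#' `n_taxa_16S` (150), `n_taxa_ITS` (150), `depth_16S` (10000),
#' `depth_ITS` (18750), `q_threshold` (0.05), `min_prevalence` (5),
#' `prevalence_filter` (0.2), `core_detection` (0.01), `core_prevalence`
#' (0.25), `n_perm` (199), `counts_16S`, `counts_ITS`, `taxonomy_16S`,
#' `taxonomy_ITS`, `metadata` (paths, required when `synthetic=false`).
#'
#' @param path config file path, or `NULL` to build from `...`.
#' @param ... key = value overrides.
#' @return named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(seed = 1, out_dir = NULL, synthetic = TRUE,
                   n_locations = 21, n_replicates = 3,
                   n_taxa_16S = 150, n_taxa_ITS = 150,
                   depth_16S = 10000, depth_ITS = 18750,
                   q_threshold = 0.05, min_prevalence = 5,
                   prevalence_filter = 0.2, core_detection = 0.01,
                   core_prevalence = 0.25, n_perm = 199,
                   counts_16S = NULL, counts_ITS = NULL,
                   taxonomy_16S = NULL, taxonomy_ITS = NULL,
                   metadata = NULL)
  vals <- defaults
  if (!is.null(path)) {
    kv <- read_truth(path)  # same key=value format
    for (k in names(kv)) {
      abort_if(!k %in% names(defaults),
               sprintf("unknown config key '%s'", k))
      v <- kv[[k]]
      vals[[k]] <- if (k %in% c("synthetic")) {
        tolower(v) %in% c("true", "1", "yes")
      } else if (k %in% c("out_dir", "counts_16S", "counts_ITS",
                          "taxonomy_16S", "taxonomy_ITS", "metadata")) {
        v
      } else as.numeric(v)
    }
  }
  dots <- list(...)
  for (k in names(dots)) {
    abort_if(!k %in% names(defaults), sprintf("unknown config key '%s'", k))
    vals[[k]] <- dots[[k]]
  }
  abort_if(is.null(vals$out_dir), "config requires out_dir")
  abort_if(vals$q_threshold <= 0 || vals$q_threshold >= 1,
           "q_threshold out of range")
  abort_if(vals$prevalence_filter < 0 || vals$prevalence_filter >= 1,
           "prevalence_filter out of range")
  abort_if(vals$core_detection <= 0 || vals$core_detection >= 1,
           "core_detection out of range")
  if (!isTRUE(vals$synthetic)) {
    for (k in c("counts_16S", "counts_ITS", "taxonomy_16S",
                "taxonomy_ITS", "metadata")) {
      abort_if(is.null(vals[[k]]),
               sprintf("config requires %s when synthetic=false", k))
      abort_if(!file.exists(vals[[k]]),
               sprintf("missing input file for %s: %s", k, vals[[k]]))
    }
  }
  structure(vals, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic generation (or input loading), table IO,
#' diversity (alpha, Bray-Curtis/PCoA, PERMANOVA, location-centered RDA),
#' metanetworks and local network properties, treatment statistics, the
#' Spearman association network with yield neighborhood, and core /
#' differential-abundance analysis. Every intermediate is written as TSV
#' under `out_dir`; `manifest.tsv` logs stage-level row/edge counts and
#' the configuration. Re-running with the same config reproduces every
#' output byte-identically.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest data.frame.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list()
  note <- function(stage, detail) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, detail = detail, stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- as.integer(config$seed)
  depths <- c("16S" = config$depth_16S, "ITS" = config$depth_ITS)

  # --- stage 1: synthgen / input loading -------------------------------
  trial <- stage("synthgen", {
    if (isTRUE(config$synthetic)) {
      des <- trial_design(n_locations = config$n_locations,
                          n_replicates_per_arm = config$n_replicates,
                          n_taxa_per_marker = c("16S" = config$n_taxa_16S,
                                                "ITS" = config$n_taxa_ITS),
                          seed = seed)
      tr <- generate_trial(des, planted_effects())
      write_truth(tr$truth, out("truth.txt"))
      tr
    } else {
      list(counts = list(
             "16S" = read_counts(config$counts_16S, "16S"),
             "ITS" = read_counts(config$counts_ITS, "ITS")),
           taxonomy = list(
             "16S" = read_taxonomy(config$taxonomy_16S, "16S"),
             "ITS" = read_taxonomy(config$taxonomy_ITS, "ITS")),
           frame = read_metadata(config$metadata), truth = NULL)
    }
  })
  note("synthgen", sprintf("samples=%d markers=%d",
                           nrow(trial$frame), length(trial$counts)))

  # --- stage 2: tables_io ---------------------------------------------
  stage("tables_io", {
    for (mk in names(trial$counts)) {
      write_counts(trial$counts[[mk]], out(sprintf("counts_%s.tsv", mk)))
      write_taxonomy(trial$taxonomy[[mk]],
                     out(sprintf("taxonomy_%s.tsv", mk)))
    }
    write_metadata(trial$frame, out("metadata.tsv"))
  })
  note("tables_io", sprintf("tables=%d", 2L * length(trial$counts) + 1L))

  # --- stage 3: diversity ---------------------------------------------
  rarefied <- list()
  stage("diversity", {
    for (mk in names(trial$counts)) {
      rt <- rarefy(trial$counts[[mk]], depths[[mk]],
                   seed = derive_seed(seed, paste0("rarefy", mk)))
      rarefied[[mk]] <- rt
      write_tsv_plain(alpha_diversity(rt), out(sprintf("alpha_%s.tsv", mk)))
      d <- bray_curtis(rt)
      ord <- pcoa(d)
      coords <- data.frame(sample_id = rownames(ord$coordinates),
                           ord$coordinates[, 1:min(4, ncol(ord$coordinates)),
                                           drop = FALSE])
      write_tsv_plain(coords, out(sprintf("pcoa_%s.tsv", mk)))
      fr <- as.data.frame(trial$frame)
      fr <- sample_frame(fr[match(rownames(d), fr$sample_id), ,
                            drop = FALSE])
      pm <- permanova(d, fr,
                      terms = c("location", "time", "location:treatment",
                                "location:time"),
                      n_perm = config$n_perm,
                      seed = derive_seed(seed, paste0("permanova", mk)))
      write_tsv_plain(pm, out(sprintf("permanova_%s.tsv", mk)))
      rda <- rda_location_centered(rt, fr, terms = c("treatment", "time"),
                                   n_perm = config$n_perm,
                                   seed = derive_seed(seed,
                                                      paste0("rda", mk)))
      write_tsv_plain(rda, out(sprintf("rda_%s.tsv", mk)))
    }
  })
  note("diversity", sprintf("rarefied=%s",
                            paste(vapply(rarefied, function(x)
                              nrow(ct_counts(x)), numeric(1)),
                              collapse = "/")))

  # --- stage 4: conet --------------------------------------------------
  metanets <- list()
  stage("conet", {
    for (mk in names(rarefied)) {
      mn <- build_metanetwork(rarefied[[mk]], depth = NULL,
                              q_threshold = config$q_threshold,
                              min_prevalence = config$min_prevalence)
      metanets[[mk]] <- mn
      write_edges(mn$edges, out(sprintf("metanetwork_%s.tsv", mk)))
      write_graphml(mn$edges, out(sprintf("metanetwork_%s.graphml", mk)),
                    nodes = mn$taxa)
    }
    props <- local_properties_all(metanets, rarefied,
                                  seed = derive_seed(seed, "localprops"))
    write_tsv_plain(props, out("local_properties.tsv"))
    write_tsv_plain(local_properties_wide(props),
                    out("local_properties_wide.tsv"))
  })
  note("conet", paste(vapply(names(metanets), function(mk)
    sprintf("%s:%d edges", mk, nrow(metanets[[mk]]$edges)), character(1)),
    collapse = " "))

  # --- stage 5: treatstats --------------------------------------------
  stage("treatstats", {
    fr <- trial$frame
    cmp <- treated_vs_control(fr, "yield", standardize = TRUE,
                              subset = fr$timepoint == "T1")
    kw <- across_locations(fr, "yield", subset = fr$timepoint == "T1")
    sum_df <- data.frame(variable = "yield", W = cmp$statistic,
                         wilcoxon_p = cmp$p, direction = cmp$direction,
                         kruskal_chi2 = kw$statistic, kruskal_p = kw$p)
    write_tsv_plain(sum_df, out("treatstats_yield.tsv"))
    write_tsv_plain(cmp$per_location, out("treatstats_yield_by_location.tsv"))
  })
  note("treatstats", "variables=yield")

  # --- stage 6: assocnet ----------------------------------------------
  stage("assocnet", {
    props <- read_tsv_plain(out("local_properties_wide.tsv"))
    fr <- as.data.frame(trial$frame)
    t1 <- fr[fr$timepoint == "T1", , drop = FALSE]
    idx <- match(t1$sample_id, props$sample_id)
    vars <- cbind(t1[, setdiff(names(t1), c("sample_id", "location",
                                            "treatment", "timepoint",
                                            "plot")), drop = FALSE],
                  props[idx, setdiff(names(props), "sample_id"),
                        drop = FALSE])
    net <- spearman_network(vars, threshold_mode = "fdr",
                            threshold = config$q_threshold,
                            seed = derive_seed(seed, "assocnet"))
    write_edges(net$edges, out("assoc_network.tsv"))
    write_tsv_plain(net$nodes, out("assoc_clusters.tsv"))
    if ("yield" %in% net$nodes$node) {
      nb <- neighborhood(net, "yield")
      write_edges(nb$edges, out("assoc_yield_neighborhood.tsv"))
    }
  })
  note("assocnet", "built")

  # --- stage 7: coreda -------------------------------------------------
  stage("coreda", {
    for (mk in names(rarefied)) {
      gt <- aggregate_to_genus(rarefied[[mk]], trial$taxonomy[[mk]])
      fr <- as.data.frame(trial$frame)
      fr <- sample_frame(fr[match(ct_samples(gt), fr$sample_id), ,
                            drop = FALSE])
      cp <- prevalence_profile(gt, fr,
                               detections = c(0.001, config$core_detection,
                                              0.05),
                               core_detection = config$core_detection,
                               core_prevalence = config$core_prevalence)
      core_df <- do.call(rbind, lapply(names(cp$core), function(g)
        data.frame(group = g, taxon = names(cp$core[[g]]),
                   core = cp$core[[g]], stringsAsFactors = FALSE)))
      rownames(core_df) <- NULL
      write_tsv_plain(core_df, out(sprintf("core_%s.tsv", mk)))
      st <- shared_taxa_constrained(gt, fr, constrained = TRUE)
      write_tsv_plain(st, out(sprintf("shared_taxa_%s.tsv", mk)))
      t1 <- fr$timepoint == "T1"
      sub <- count_table(ct_counts(gt)[t1, , drop = FALSE], gt$marker)
      da <- nb_differential_abundance(sub, fr)
      write_tsv_plain(as.data.frame(da), out(sprintf("da_%s.tsv", mk)))
    }
  })
  note("coreda", "done")

  cfg <- unclass(config)
  cfg <- cfg[setdiff(names(cfg), "out_dir")]  # keep manifest path-free
  cfg_df <- data.frame(stage = "config",
                       detail = paste(names(cfg),
                                      vapply(cfg, function(v)
                                        paste(as.character(v %||% ""),
                                              collapse = ","),
                                        character(1)),
                                      sep = "=", collapse = ";"))
  man <- rbind(do.call(rbind, manifest), cfg_df)
  write_tsv_plain(man, out("manifest.tsv"))
  invisible(man)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher used by the `potatonet` script in
#' `inst/scripts/`: `potatonet run --config run.cfg` runs the full
#' pipeline; `potatonet generate --out dir --seed 1` writes a synthetic
#' trial.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
potatonet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: potatonet <run|generate> [options]",
    "  run      --config <file>",
    "  generate --out <dir> [--seed <int>] [--locations <n>]", sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  if (cmd == "run") {
    abort_if(is.null(opt$config), "run requires --config")
    run_all(run_config(opt$config))
  } else if (cmd == "generate") {
    abort_if(is.null(opt$out), "generate requires --out")
    seed <- as.integer(opt$seed %||% 1)
    nl <- as.integer(opt$locations %||% 21)
    tr <- generate_trial(trial_design(n_locations = nl, seed = seed))
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    for (mk in names(tr$counts)) {
      write_counts(tr$counts[[mk]],
                   file.path(opt$out, sprintf("counts_%s.tsv", mk)))
      write_taxonomy(tr$taxonomy[[mk]],
                     file.path(opt$out, sprintf("taxonomy_%s.tsv", mk)))
    }
    write_metadata(tr$frame, file.path(opt$out, "metadata.tsv"))
    write_truth(tr$truth, file.path(opt$out, "truth.txt"))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    abort_if(!startsWith(a, "--"), sprintf("unexpected argument '%s'", a))
    abort_if(i == length(args), sprintf("option %s needs a value", a))
    opt[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}
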