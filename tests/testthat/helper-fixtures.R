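# Small shared fixtures, built in code.

toy_counts <- function(m = NULL, marker = "16S") {
  if (is.null(m)) {
    m <- matrix(c(5, 0, 3,
                  2, 2, 2,
                  0, 7, 1), nrow = 3, byrow = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  count_table(m, marker)
}

toy_frame <- function(n_loc = 2, reps = 2, timepoints = c("T0", "T1"),
                      seed = 1) {
  set.seed(seed)
  g <- expand.grid(timepoint = timepoints, replicate = seq_len(reps),
                   treatment = c("control", "treated"),
                   location = sprintf("L%02d", seq_len(n_loc)),
                   stringsAsFactors = FALSE)
  g$plot <- sprintf("%s_%s_r%d", g$location, g$treatment, g$replicate)
  g$sample_id <- sprintf("%s_%s", g$plot, g$timepoint)
  g$yield <- ifelse(g$timepoint == "T1", rnorm(nrow(g), 400, 30), NA)
  sample_frame(g[, c("sample_id", "location", "treatment", "timepoint",
                     "plot", "yield")])
}

# NB count simulator for the differential-abundance checks: two arms,
# log-uniform baseline means, optional fold change on the first n_fc taxa
sim_da_counts <- function(seed, n_per_arm = 30, n_taxa = 40, fc = 1,
                          n_fc = 8, dispersion = 0.2) {
  set.seed(seed)
  mu <- exp(runif(n_taxa, log(5), log(200)))
  m <- vapply(seq_len(n_taxa), function(j) {
    mm <- rep(mu[j], 2 * n_per_arm)
    if (fc != 1 && j <= n_fc) mm[(n_per_arm + 1):(2 * n_per_arm)] <-
        mm[(n_per_arm + 1):(2 * n_per_arm)] * fc
    stats::rnbinom(2 * n_per_arm, mu = mm, size = 1 / dispersion)
  }, numeric(2 * n_per_arm))
  rownames(m) <- paste0("s", seq_len(2 * n_per_arm))
  colnames(m) <- paste0("t", seq_len(n_taxa))
  fr <- sample_frame(data.frame(
    sample_id = rownames(m), location = "L1",
    treatment = rep(c("control", "treated"), each = n_per_arm),
    timepoint = "T1"))
  list(table = count_table(m, "16S"), frame = fr)
}

small_trial <- function(seed = 1, markers = "16S", n_loc = 4, reps = 2,
                        n_taxa = 40, libs = c(2000, 3000),
                        effects = planted_effects(n_cooccur_pairs = 2,
                                                  n_coexclude_pairs = 2,
                                                  n_treated_taxa = 5,
                                                  treated_marker =
                                                    if ("ITS" %in% markers)
                                                      "ITS" else NULL)) {
  nt <- stats::setNames(rep(n_taxa, length(markers)), markers)
  generate_trial(trial_design(n_locations = n_loc,
                              n_replicates_per_arm = reps,
                              markers = markers, n_taxa_per_marker = nt,
                              library_size_range = libs, seed = seed),
                 effects)
}
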