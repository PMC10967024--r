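test_that("rarefy subsamples exactly, drops shallow samples, is seeded", {
  m <- matrix(c(60, 40, 0,
                10, 10, 10,
                2, 2, 1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  ct <- count_table(m, "16S")
  r <- rarefy(ct, 40, seed = 11)
  expect_equal(attr(r, "dropped"), c("s2", "s3"))
  expect_equal(unname(rowSums(ct_counts(r))), 40)
  # total exactly depth -> unchanged (s2 totals 30)
  r2 <- rarefy(ct, 30, seed = 1)
  expect_equal(ct_counts(r2)["s2", ], m["s2", ])
  # determinism
  expect_identical(ct_counts(rarefy(ct, 40, seed = 11)), ct_counts(r))
  expect_false(identical(ct_counts(rarefy(ct, 25, seed = 12))["s1", ],
                         ct_counts(rarefy(ct, 25, seed = 11))["s1", ]))
  expect_error(rarefy(ct, 1000), "all samples below depth")
})

test_that("rarefaction curve matches the hypergeometric expectation", {
  # closed form: E[S_d] = sum_i 1 - C(N - N_i, d) / C(N, d)
  x <- c(12, 6, 2, 1)
  N <- sum(x); d <- 10
  exp_rich <- sum(1 - choose(N - x, d) / choose(N, d))
  m <- matrix(x, nrow = 1, dimnames = list("s1", paste0("t", 1:4)))
  rc <- rarefaction_curve(count_table(m, "16S"), depths = c(5, 10),
                          n_draws = 400, seed = 3)
  got <- rc$richness[rc$depth == 10]
  # SE of the mean over draws, estimated with the package subsampler
  set.seed(99)
  se <- sd(replicate(50, sum(potatonet:::subsample_counts(x, d) > 0))) /
    sqrt(400)
  expect_lt(abs(got - exp_rich), max(4 * se, 0.05))
  # depth = total -> observed richness exactly
  rc2 <- rarefaction_curve(count_table(m, "16S"), depths = N, n_draws = 3,
                           seed = 1)
  expect_equal(rc2$richness, 4)
  # single-taxon sample: richness 1 at all depths
  m1 <- matrix(20, 1, 1, dimnames = list("s1", "t1"))
  rc3 <- rarefaction_curve(count_table(m1, "16S"), depths = c(1, 5, 20),
                           n_draws = 5, seed = 1)
  expect_equal(rc3$richness, c(1, 1, 1))
})

test_that("alpha diversity matches hand-computed values", {
  m <- rbind(s1 = c(2, 2, 2), s2 = c(1, 1, 2), s3 = c(5, 5, 5),
             s4 = c(0, 0, 0))
  colnames(m) <- paste0("t", 1:3)
  a <- alpha_diversity(count_table(m, "16S"))
  expect_equal(a$chao1[a$sample_id == "s1"], 3)        # no singletons
  expect_equal(a$chao1[a$sample_id == "s2"], 3.5)      # F1=2, F2=1
  expect_equal(a$shannon[a$sample_id == "s3"], log(3))
  expect_true(is.na(a$shannon[a$sample_id == "s4"]))   # empty sample
  m4 <- matrix(c(5, 5, 5, 5), 1, dimnames = list("s", paste0("t", 1:4)))
  expect_equal(alpha_diversity(count_table(m4, "16S"))$shannon, log(4))
})

test_that("bray-curtis follows the formula and is scale invariant", {
  m <- rbind(a = c(10, 0), b = c(5, 5))
  colnames(m) <- c("t1", "t2")
  d <- bray_curtis(count_table(m, "16S"))
  expect_equal(d["a", "b"], 0.5)   # sum|p-q| / 2 on proportions
  expect_equal(diag(d), c(a = 0, b = 0))
  # disjoint supports -> 1; identical samples -> 0
  m2 <- rbind(a = c(3, 0, 0), b = c(0, 2, 5), c = c(6, 0, 0))
  colnames(m2) <- paste0("t", 1:3)
  d2 <- bray_curtis(count_table(m2, "16S"))
  expect_equal(d2["a", "b"], 1)
  expect_equal(d2["a", "c"], 0)
  # invariance to library rescaling
  m3 <- m2 * 7
  expect_equal(bray_curtis(count_table(m3, "16S")), d2)
  mz <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(bray_curtis(count_table(mz, "16S")), "zero-total")
})

test_that("pcoa reproduces Euclidean geometry and centers coordinates", {
  set.seed(7)
  X <- matrix(rnorm(8 * 3), 8, 3)
  rownames(X) <- paste0("s", 1:8)
  d <- as.matrix(dist(X))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_lt(max(abs(colMeans(ord$coordinates))), 1e-10)
  expect_true(all(diff(ord$eigenvalues) <= 1e-10))
  # 3 equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord3 <- pcoa(d3)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-10]
  expect_equal(pos[1], pos[2])
  # 2 samples: one axis carrying all variance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoa(d2)
  expect_equal(ncol(ord2$coordinates), 1)
  expect_equal(ord2$prop_explained, 1)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "asymmetric")
})

test_that("permanova agrees with vegan::adonis2 and partitions to 100%", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(rpois(24 * 12, 15), 24, 12,
              dimnames = list(paste0("s", 1:24), paste0("t", 1:12)))
  fr <- sample_frame(data.frame(
    sample_id = paste0("s", 1:24),
    location = rep(c("A", "B", "C"), each = 8),
    treatment = rep(c("control", "treated"), 12),
    timepoint = rep(rep(c("T0", "T1"), each = 2), 6)))
  ct <- count_table(m, "16S")
  d <- bray_curtis(ct)
  pm <- permanova(d, fr, c("location", "treatment", "location:treatment"),
                  n_perm = 99, seed = 4)
  ad <- vegan::adonis2(as.dist(d) ~ location + treatment +
                         location:treatment,
                       data = as.data.frame(fr), by = "terms",
                       permutations = 99)
  expect_equal(pm$SS[1:3], ad$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(pm$pseudo_F[1:3], ad$F[1:3], tolerance = 1e-10)
  expect_equal(sum(pm$R2), 100, tolerance = 1e-6)
  # duplicating every sample leaves the R2 partition unchanged
  idx <- rep(seq_len(24), 2)
  m2 <- m[idx, ]; rownames(m2) <- paste0("s", 1:48)
  fr2 <- as.data.frame(fr)[idx, ]; fr2$sample_id <- paste0("s", 1:48)
  d2 <- bray_curtis(count_table(m2, "16S"))
  pm2 <- permanova(d2, sample_frame(fr2),
                   c("location", "treatment", "location:treatment"),
                   n_perm = 19, seed = 1)
  expect_equal(pm2$R2, pm$R2, tolerance = 1e-8)
  expect_error(permanova(d, fr, "nope", n_perm = 9), "unknown term")
})

test_that("permanova p-values are seeded and in (0, 1]", {
  tr <- small_trial(seed = 31, n_loc = 3, reps = 2, n_taxa = 20,
                    libs = c(500, 600))
  d <- bray_curtis(tr$counts[["16S"]])
  p1 <- permanova(d, tr$frame, c("location", "time"), n_perm = 49,
                  seed = 9)
  p2 <- permanova(d, tr$frame, c("location", "time"), n_perm = 49,
                  seed = 9)
  expect_identical(p1$p, p2$p)
  expect_true(all(p1$p[1:2] > 0 & p1$p[1:2] <= 1))
  # strata mode runs and stays in range
  p3 <- permanova(d, tr$frame, c("location", "time"), n_perm = 49,
                  seed = 9, strata = "location")
  expect_true(all(p3$p[1:2] > 0 & p3$p[1:2] <= 1))
})

test_that("fit_vectors: perfect axis alignment gives R2 = 1", {
  set.seed(13)
  X <- matrix(rnorm(12 * 3), 12, 3)
  rownames(X) <- paste0("s", 1:12)
  ord <- pcoa(as.matrix(dist(X)))
  fr <- data.frame(sample_id = rownames(X),
                   location = "L1", treatment = "control",
                   timepoint = "T0",
                   ax = ord$coordinates[, 1],
                   noise = rnorm(12),
                   withna = c(NA, rnorm(11)))
  fr <- sample_frame(fr)
  fv <- suppressWarnings(fit_vectors(ord, fr, c("ax", "noise", "withna"),
                                     n_perm = 99, seed = 2))
  expect_equal(fv$R2[1], 1, tolerance = 1e-10)
  expect_equal(fv$p[1], 0.01)
  expect_equal(fv$n_used[3], 11)  # complete cases only
  expect_error(fit_vectors(ord, fr, "nope"), "unknown variable")
  fr2 <- as.data.frame(fr); fr2$flat <- 1
  expect_error(fit_vectors(ord, sample_frame(fr2), "flat"), "constant")
})

test_that("location-only variation is annihilated by location centering", {
  tr <- small_trial(seed = 17, n_loc = 4, reps = 2, n_taxa = 25,
                    libs = c(1000, 1200), effects = planted_effects(
                      location_concentration = 5, n_cooccur_pairs = 0,
                      n_coexclude_pairs = 0, treated_marker = NULL,
                      n_treated_taxa = 0))
  rda <- rda_location_centered(tr$counts[["16S"]], tr$frame,
                               c("treatment", "time"), n_perm = 49,
                               seed = 3)
  # location variance is gone: both terms explain almost nothing
  expect_lt(sum(rda$R2[1:2]), 10)
  expect_equal(sum(rda$R2), 100, tolerance = 1e-6)
  fr2 <- as.data.frame(tr$frame)
  fr2$dupe <- as.numeric(fr2$treatment == "treated")  # collinear with arm
  expect_error(rda_location_centered(
    tr$counts[["16S"]], sample_frame(fr2), c("treatment", "dupe"),
    n_perm = 9), "singular")
})
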