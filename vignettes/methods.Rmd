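---
title: "Models and methods: metanetworks, treatment tests, and the synthetic trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery:
the models, the defaults and why they are what they are, what the
synthetic generator does and does not emulate, and where the design was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. The signed presence–absence metanetwork

For one marker (16S or ITS), presence is called on rarefied counts
(`rarefied count > 0`). For a taxon pair with margins $n_A$, $n_B$ in
$N$ samples and observed co-presence $k$, independence with fixed
margins gives $X \sim \mathrm{Hypergeometric}(N, n_A, n_B)$,
$\mathbb{E}[X] = n_A n_B / N$. The one-sided tails
$p_{\mathrm{more}} = P(X \ge k)$ and $p_{\mathrm{less}} = P(X \le k)$
support co-occurrence and co-exclusion respectively.

*Null model choice.* The source methodology names no explicit test for
"more or fewer than expected by chance"; the hypergeometric
(Fisher-exact / probabilistic co-occurrence) model is the standard
choice for binary co-occurrence with fixed margins and is analytic,
fast, and exact. A fixed-margin permutation alternative (checkerboard
swaps preserving row and column sums) is available via
`build_metanetwork(..., null_model = "swap")`; it converges to the
hypergeometric verdicts but at permutation-resolution p-values, so it
is a cross-check, not the default.

*Multiplicity.* Benjamini–Hochberg is applied across the union of both
one-sided families within a marker (2 × number of pairs), and edges
keep the tail with $q$ below the threshold (default $q < 0.05$; the
source states FDR correction but no threshold for metanetwork edges —
0.05 is the conventional default and is configurable). A pair can never
earn both signs since $p_{\mathrm{more}} + p_{\mathrm{less}} \ge 1$.

*Prevalence pre-filter.* Taxa present in fewer than 5 or more than
$N-5$ samples are excluded (default, configurable): degenerate margins
(0 or $N$) make the test undefined, and near-degenerate margins make
one tail untestable. This is why the filter is symmetric.

## 2. Per-sample local network properties

The metanetwork is built once from all samples; each sample then
induces a subgraph on its present taxa, restricted to one edge sign,
and three properties are computed:

* **Transitivity**: $3 \cdot \#\text{triangles} / \#\text{connected
  triples}$, defined as 0 when the subgraph has connected triples but
  no triangles is automatic; when there are *no connected triples at
  all* we also report 0 (a star-free, triangle-free graph is maximally
  non-clustered, and `NaN` would poison downstream correlation
  columns). When the subgraph has no edges every property is `NA`, not
  zero — absence of evidence is recorded as missing.
* **Average path length**: the mean shortest-path distance over pairs
  *within connected components*. Induced subgraphs are frequently
  disconnected; conventions that assign infinite or $n$-based
  distances to disconnected pairs would make the index dominated by
  component count rather than path structure. The within-component
  mean is what `igraph::mean_distance(unconnected = TRUE)` computes.
* **Modularity**: the best Louvain $Q$ over 10 restarts (vertex order
  randomized between restarts under a derived seed). Louvain is
  stochastic and greedy; restart-max both stabilizes the value and, on
  the ≤ 8-node graphs where we can enumerate all partitions, attains
  the exhaustive maximum in ≥ 95% of instances (asserted in the
  acceptance suite).

Presence for the per-sample subsetting uses rarefied counts, matching
the metanetwork's presence definition: using raw counts on one side
would let library size leak into the network indexes.

## 3. Diversity, ordination, PERMANOVA, RDA

Alpha diversity: observed richness, Shannon $-\sum p_i \ln p_i$, and
bias-corrected Chao1 $S + F_1(F_1-1) / (2(F_2+1))$. Rarefaction is
multivariate-hypergeometric subsampling without replacement to exact
depth, with defaults of 10,000 reads (16S) and 18,750 (ITS) — the
depths the genus-level analyses use; samples below depth are dropped
and reported. Bray–Curtis is computed on relative abundances, making
it library-size invariant.

PCoA is classical Gower double-centering plus eigendecomposition.
Negative eigenvalues are reported but uncorrected (no Lingoes/Cailliez
adjustment), and variance fractions are taken over positive eigenvalues
only: Bray–Curtis is non-Euclidean, and silently "fixing" the geometry
would change coordinates that downstream vector fitting depends on.

PERMANOVA uses sequential (Type I) partitioning in the listed term
order — the source reports nested terms (location, time,
location:treatment, location:time, location:treatment:time) which only
make sense sequentially — with pseudo-$F$ per term and
$p = (1 + \#\{F^\ast \ge F\}) / (1 + n_{\mathrm{perm}})$ under free
permutation of sample labels. Whether the published analysis permuted
within location strata is unstated; free permutation is the default and
`strata = "location"` provides the restricted variant. The $R^2$
values (as percentages) plus the residual sum to 100 exactly, by
construction of the trace decomposition. The implementation is checked
against `vegan::adonis2(by = "terms")` in the unit tests.

Vector fitting regresses each numeric variable on the first two
ordination axes (matching two-dimensional ordination figures),
permuting the variable for $p$; complete cases only, with $n$
reported.

The location-centered RDA log-transforms counts (`log(1+count)`),
subtracts each location's mean taxon profile — removing the location
effect exactly, which is the point: treatment variance is ~2% while
location variance is ~50% — and fits the sequential term design by
least squares. Per-term significance permutes residuals under the
reduced model (all preceding terms), the standard guard against
nuisance-term leakage in multivariate linear permutation tests. The
residual rows are permuted *within location strata*: centering forces
every location block to sum to zero, so rows are exchangeable only
within a location, and free permutation is measurably anticonservative
(empirical type-I ~0.11 at nominal 0.05 in a 200-trial null
simulation during development; ~0.055 with the stratified set).

## 4. Treatment statistics

Z-scores are computed per location over both arms pooled. Per-arm
standardization would subtract the treatment effect itself; pooling is
the only reading under which the test retains power, so it is the
default and documented as such.

With 3+3 sub-plots per location, per-location centering induces
within-location dependence (each location's six standardized values
sum to zero), and the classical asymptotic rank-sum p-value becomes
anticonservative by roughly two points of type-I error — we measured
~0.077 at nominal 0.05 in a direct simulation, and the effect does not
vanish with more locations. The package therefore computes the
p-value for the usual rank-sum statistic from its permutation
distribution under within-location relabeling of arms — the exact null
for a location-blocked design (the classical Wilcoxon test is itself
the free-permutation special case). `p_method = "asymptotic"` restores
the textbook approximation. The Kruskal–Wallis across-location test and
the unpaired (rank-sum, not signed-rank) choice follow the trial
design: sub-plots are not described as paired across arms.

Net-change comparisons match T0/T1 values per physical sub-plot
(`plot` column), take $\Delta = v_{T1} - v_{T0}$, and run the same
standardized comparison on the deltas; unmatched plots are dropped and
reported.

## 5. Association network and degree tests

Pairwise Spearman on pairwise-complete observations (minimum 8),
average ranks for ties, two-sided $p$ from the $t$ approximation (an
exact permutation option exists for very small $n$), BH across all
pairs. The edge threshold defaults to $q < 0.05$; the source's figure
states raw $p < 0.05$ while its methods state FDR correction, so both
are implemented (`threshold_mode = "fdr"` / `"p"`). Louvain clusters
are computed on the positive-edge subgraph weighted by $|\rho|$,
mirroring clustering of positive associations only.

The prevalence-conditional degree test bins nodes into equal-frequency
prevalence bins (default 10, singleton bins merged), sets each node's
expected degree to its bin's mean degree, sums observed-minus-expected
over a unit (taxon or clade), and permutes degrees within bins for a
two-sided $p$. The source describes "higher or lower degree than
expected given prevalence" without naming the null; binning was chosen
over a parametric degree~prevalence regression because it makes no
shape assumption, and the bin count is configurable. This choice is
documented, not asserted as the original authors'.

## 6. Core microbiome and differential abundance

Detection thresholds are on relative abundance (0.01 read as 1%),
following standard core-microbiome heatmap tooling; core membership at
detection 0.01 requires prevalence ≥ 25% in the group *and* detection
in every location — the all-locations rule is what distinguishes a
"conserved" member from a locally dominant one. Shared-taxa counts
between arms are location-constrained: a taxon is shared only when
co-detected in control and treated samples of at least one common
location (an unconstrained mode exists; the constrained reading is one
interpretation of "intersections constrained by location" and is
flagged as such).

Differential abundance is plain per-taxon negative-binomial regression:
median-of-ratios size factors (library-size fallback when no taxon is
everywhere positive), `count ~ treatment` with a log size-factor
offset, ML dispersion via `MASS::glm.nb` with a method-of-moments
fallback (floored at $10^{-8}$), Wald test on the treatment
coefficient, BH across tested taxa. No shrinkage of dispersions or fold
changes is applied — results will differ from shrinkage-based NB
frameworks, deliberately: the package implements the unshrunk model and
documents the fallbacks. Taxa with totals below 10 are not tested;
taxa all-zero in one arm are flagged untestable by default, or tested
with a +0.5 continuity correction under
`zero_arm_policy = "pseudo"`.

## 7. The synthetic trial generator

The generator's defaults are a stated world calibrated to the
qualitative structure of a 21-location biostimulant trial; the source
reports no per-location effect sizes, so magnitudes were fixed once (a
small pilot of 8 generations, run before the acceptance suite was
written) and not revisited:

* **Compositions.** A global log-normal taxon profile $g$; location
  mean compositions $\sim \mathrm{Dirichlet}(25\,g)$ (total
  concentration 25 — strongly divergent locations, reproducing the
  location-dominant variance pattern); per-sample compositions
  $\sim \mathrm{Dirichlet}(200\,p_{\mathrm{loc}})$; counts multinomial
  at a library size drawn uniformly from 20,000–35,000 (above the
  deepest rarefaction depth used downstream). Row sums equal library
  sizes exactly.
* **Treatment.** A 4-fold multiplicative shift on the 20 most
  globally abundant fungal (ITS) taxa, applied in treated-T1 cells
  only. Abundant taxa are chosen so the shift is observable in most
  locations despite the divergent location profiles.
* **Planted pairs.** Pair members follow a shared Bernoulli(0.5)
  latent factor with probability 0.9 (else an independent coin);
  co-excluding members follow opposite factors. Present members get a
  compositional weight of 5× the mean taxon weight, absent members
  exactly 0, so presence tracks the latent factor through rarefaction.
* **Yield.** Only at T1: location base $\sim N(400, 60)$ cwt/ac,
  +15% of the location base under treatment, a designated
  "connectivity" proxy covariate with coefficient 30, a small soil
  calcium term, Gaussian noise sd 30.
* **Covariates.** Soil/petiole/environmental variables with
  location-specific means; petiole and yield exist only at T1,
  mirroring harvest-side measurement.

What the generator does **not** emulate: sequence-level error or
chimeras (no FASTQ), spatial field structure within locations, weather
time series, taxon phylogeny, compositional interactions beyond the
planted pairs, and any real taxon identity. A green recovery test
therefore establishes that the pipeline detects the planted structure
in a world with these statistical features — not that the original
field results are reproduced.

## 8. Numerical and testing choices

* All randomness flows through per-stage seeds derived from a single
  user seed; reruns are byte-identical (asserted end-to-end).
* TSV writers print numerics with `%.17g`, guaranteeing lossless
  round trips; missing values are literal `NA`; taxa-as-rows is the
  canonical count-table orientation with a transpose flag on read.
* Permutation p-values always use the add-one estimator
  $(1+\#)/(1+B)$, so they are in $(0, 1]$ and never exactly zero.
* The acceptance suite's graph oracle is exhaustive over all labelled
  connected graphs on ≤ 5 nodes (1,044 graphs) plus seeded random
  samples at 6–8 nodes; full enumeration at 8 nodes (~2.5·10⁸ graphs)
  is outside the time budget. Max-modularity enumeration uses
  restricted-growth-string partitions (Bell(8) = 4,140).
* Type-I simulations use compact designs (6–8 locations, 30–40 taxa,
  99–199 permutations) to fit a 1-CPU budget; recovery simulations use
  the stated sizes (120 samples for pair recovery, 20 locations × 3+3
  for yield, 30/arm at dispersion 0.2 for differential abundance).

## 9. Known limitations

* The hypergeometric pair test conditions on margins; location-driven
  joint prevalence produces real (not spurious, but uninteresting)
  edges, as in any presence–absence co-occurrence analysis. The
  package does not de-confound the metanetwork by location.
* The NB Wald test without shrinkage is anticonservative at very small
  per-arm counts; the `min_count_filter` default (total ≥ 10) is the
  guard.
* `fit_vectors` uses the first two axes only; variance on higher axes
  is invisible to it, by design (it mirrors 2-D ordination figures).
* The swap-model null uses a fixed burn-in heuristic (5× fill) without
  a formal mixing diagnostic; it is intended as a cross-check of the
  analytic null, not a primary inference route.
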