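---
title: "Methods: phylogenetically informed boosted regression trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically informed boosted regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`phylobrt` addresses a comparative question: given one continuous
sensitivity value per species (here a transformed in vitro TCDD EC50
standing in for a receptor subtype), how much of the interspecies
variation is associated with measurable life-history traits, and how much
with shared ancestry alone?

Species data violate the independence assumption of ordinary regression.
Instead of a parametric phylogenetic regression (e.g. PGLS, which commits
to an evolutionary covariance model), the pipeline uses *phylogenetic
eigenvector regression*: the patristic distance matrix of a consensus
phylogeny is converted to principal coordinates, and the leading
coordinates — axes of relatedness — enter a flexible learner as ordinary
covariates next to the traits. The learner is a least-squares boosted
regression tree ensemble

\[
\hat f(x) \;=\; \bar y \;+\; \nu \sum_{m=1}^{M} T_m(x),
\]

where each \(T_m\) is a small regression tree fit to the current
residuals on a bagged subsample, \(\nu\) is the shrinkage (learning
rate), and \(M\) is chosen to minimise the \(k\)-fold cross-validated
predictive squared-error deviance. Trees accommodate nonlinearities,
mixed predictor types and missing values without preprocessing, which is
what makes the joint ranking of traits and eigenvectors practical.

Each split stores its squared-error improvement. Relative-influence
variable importance (VI) sums those improvements per predictor over the
selected ensemble and rescales the scores to sum to 100; a predictor
never used in a split scores exactly 0. The headline *deviance
partition* follows: if the model explains \(T\) percent of the response
deviance (we report the cross-validated figure as primary, the training
figure alongside), and a predictor group (traits, phylogeny) carries
\(g\) percent of the VI mass, its absolute share of the response
deviance is \(T \times g / 100\). The shares add up to \(T\) by
construction.

## Pipeline stages and their assumptions

**Consensus.** The tree set (e.g. posterior samples) is summarised by
strict majority rule: the consensus contains exactly the clades whose
frequency is *strictly greater than* the threshold (default 0.5). At
0.5 this guarantees pairwise compatibility; clades at exactly 50% are
excluded. Consensus branch lengths are arithmetic means over the trees
containing the clade (tip branches average over all trees); unresolved
regions become polytomies. The strict inequality and the mean-length
rule are declared defaults — summary tools differ here, and neither
choice affects clades with clear majorities.

**Patristic distances and principal coordinates.** Distances are path
sums of branch lengths. PCoA double-centres \(-\tfrac12 D^2\) (Gower)
and eigendecomposes the result. Patristic distances need not be
Euclidean-embeddable, so negative eigenvalues can occur: they are
recorded but excluded from the coordinates, and explained fractions are
computed over positive eigenvalues only (no Lingoes/Cailliez
correction). Axis signs are arbitrary in any eigendecomposition; we fix
them by making the largest-magnitude loading positive so runs are
reproducible across platforms. Eigenvector selection takes the smallest
prefix of axes whose cumulative explained fraction reaches the
threshold; the default 0.99 reflects the analysis this package
implements, with 0.95 the conventional floor in the eigenvector
regression literature. Selection is monotone in the threshold.

**Trait table.** Seventeen traits in three kinds: continuous (periods in
days, masses in grams, clutch size in eggs, lifespan in years, migration
distance in degrees latitude, percent clutch mass), ordered categoricals
carried as integer ranks (breeding/wintering range 1–5, coloniality
0–2), and unordered categoricals carried as level codes (stage at hatch,
migration route, mating system, habitat, foraging guild) — no dummy
expansion, since the tree learner splits on level subsets directly. Two
traits are derived: *residual testes mass* is the OLS residual of log10
testes mass on log10 body mass over complete cases (the allometric
convention; a raw-scale switch exists), and *migration distance* is the
absolute difference of breeding and wintering latitudinal midpoints
(midpoints may be given directly or as north/south extents, in which
case the midpoint is their mean). Note the source material prints
migration distance in km while defining it in degrees latitude; the
package uses degrees throughout.

**Response.** Each species maps to its subtype's EC50. The default
transform is the z-score of log10 EC50 across species: EC50 spans
several orders of magnitude, log10 linearises that span, and z-scoring
makes the response dimensionless. The transform is monotone, so species
of one subtype share one response value and larger EC50 (lower
sensitivity) always maps to a larger response. `raw` and plain `log10`
switches exist. A single-subtype response is degenerate and is an error.

**Missing values.** Trait cells may be missing; they are passed to the
learner, which routes rows with a missing split value to the child
holding more rows (deterministic, recorded per node) — no surrogate
splits, no imputation. Eigenvector scores are complete by construction.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `consensus_threshold` | 0.5 | clade-frequency cutoff (strict) |
| `eigen_threshold` | 0.99 | cumulative explained-variation target |
| `learning_rate` | 0.01 | shrinkage per tree |
| `tree_complexity` | 3 | max splits per tree (depth ≤ 3) |
| `bag_fraction` | 0.75 | rows subsampled per tree, without replacement |
| `n_folds` | 10 | cross-validation folds, stratified on response quantiles |
| `step_size` | 50 | trees between CV evaluations |
| `max_trees` | 10,000 | ensemble-size cap |
| `cv_patience` | 10 | CV evaluations without improvement before stopping |

The boosting defaults follow the `gbm.step` tradition for ecological
BRTs; tree complexity 3 permits (and the interaction screen then tests
for) low-order interactions. The underlying analysis did not publish its
hyperparameters, so these are declared package defaults, all exposed in
`brt_config()`.

## Numerical choices

- Split search: continuous and ordered columns scan midpoint thresholds
  between adjacent distinct values; nominal columns search level subsets
  exhaustively up to 10 levels (covering the 10-level habitat trait) and
  fall back to a mean-ordered scan above that. A split must reduce the
  node SSE by more than 1e−12 to be accepted.
- Ties in the split search are broken deterministically: lowest column
  index, then lowest threshold (lowest subset mask for nominal splits).
  A consequence worth knowing: in the interpolation regime (very many
  trees, near-zero residuals) two columns can offer *bitwise identical*
  gains by isolating the same rows, and VI attribution then depends on
  column order. Away from that regime, VI is invariant to predictor
  order, and the test suite checks it there.
- Best-first growth: each step splits the leaf with the largest gain
  (earliest-created leaf wins ties), up to `tree_complexity` splits, so
  tree depth never exceeds the complexity. Greedy step optimality is
  verified against exhaustive split enumeration in the tests; note that
  a greedy sequence need not match a globally optimal two-split search,
  which is why the oracle validates each step rather than the sequence.
- Reproducibility: fold assignment and bagging draw from R's RNG, so a
  fixed `rng_seed` gives bit-identical ensembles; model JSON
  serialisation uses 17 significant digits so a reloaded model
  reproduces predictions, VI and partitions exactly.
- Degenerate inputs: constant residuals yield a single-leaf tree (not an
  error); a model whose splits never improve the fit returns uniform VI
  with a warning; a zero-variance response, an empty tree set, and
  mismatched species sets are errors that name the offending stage or
  species.

## The synthetic-data generator

`simulate_dataset()` emulates the *structure* of the real study: one
Yule (pure-birth) tree with 89 tips; a tree set made of that tree plus
NNI-perturbed replicates (so consensus has genuine work to do); nine
continuous traits evolved by Brownian motion; three ordered and five
unordered categorical traits evolved by a symmetric Mk jump process
(closed-form transition probabilities, uniform root state); and a latent
response \(\sqrt{1-w}\,s_{\text{traits}} + \sqrt{w}\,s_{\text{BM}} +
\varepsilon\) with both signal components standardised, discretised by
quantiles into up to 13 subtypes whose EC50s sit on a log-spaced grid
spanning three orders of magnitude — mirroring the up-to-1,000-fold
sensitivity range. Defaults: two nonzero trait effects (1 and 0.5),
phylogenetic weight 0.3, noise SD 0.3, 5% missingness completely at
random, 20 trees with 2 NNI moves each.

What it does *not* emulate: realistic avian life-history covariance
among traits (traits evolve independently), non-Brownian evolution,
informative missingness, posterior tree-set heterogeneity beyond local
NNI moves, or the actual trait–subtype associations of the real data.
Passing recovery tests therefore shows the pipeline attributes variance
to the right *source* (a known trait driver, or pure relatedness) under
its own generative assumptions — not that the published real-data
numbers are reproduced. Those depend on the deposited dataset, the
original tree set, and unreported hyperparameters, and are out of reach
at desk scale by design.

## Problem sizes in the test suite

The suite exercises the full study structure (89 tips, 17 traits, up to
13 subtypes) in the end-to-end and recovery tests (10 seeds per recovery
scenario), exhaustive oracles at small sizes where enumeration is exact
(trees of ≤ 8 tips for consensus, n ≤ 12 instances for split search),
simulation cross-checks at 200–500 rows, and Monte-Carlo checks of the
generators (hundreds to thousands of replicates). These sizes are chosen
so each check is informative while the whole suite stays quick to run.

## Known limitations

- Gaussian (squared-error) loss only; no Bernoulli/Poisson families,
  monotonicity constraints, or multithreading.
- The interaction screen is descriptive (residual variance of the
  bivariate partial-dependence surface after removing additive row and
  column effects); no significance test is attached, deliberately.
- Majority-rule consensus treats trees as rooted; no rerooting or
  dating.
- With heavy missingness the heavier-child routing can bias leaf
  assignment; surrogate splits were considered and rejected for
  simplicity and determinism.
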