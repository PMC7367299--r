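# phylobrt

Boosted regression trees (BRTs) for phylogenetic comparative analysis:
rank species traits against phylogenetic eigenvectors as correlates of a
continuous species-sensitivity proxy, and partition the explained deviance
into trait and phylogeny components.

## The problem

Avian species differ by up to a thousand-fold in their sensitivity to
dioxin-like compounds, and that sensitivity tracks the ligand-binding
domain (LBD) of the aryl hydrocarbon receptor 1 (AHR1): amino acids at a
handful of sites define 13 receptor subtypes, each with a measured in
vitro TCDD EC50. A natural comparative question follows: which species
traits, and how much shared ancestry, predict where a species falls on
that sensitivity spectrum? Species are not independent observations —
relatives resemble each other — so any trait analysis must account for
phylogenetic non-independence.

`phylobrt` implements the full analysis as a reusable, tested pipeline:

1. **Consensus tree** — a set of candidate phylogenies (e.g. 1,000
   posterior trees) is summarised into a 50% majority-rule consensus with
   branch lengths averaged over the supporting trees.
2. **Phylogenetic eigenvectors (PVR)** — the patristic distance matrix
   *D* of the consensus is double-centred
   (*B = −½ J D² J*) and eigendecomposed; the leading principal
   coordinates, enough to explain ≥ 99% of the phylogenetic structure,
   enter the model as covariates alongside the traits.
3. **Boosted regression trees** — a from-scratch least-squares gradient
   booster (shrinkage ν = 0.01, tree complexity 3, bag fraction 0.75,
   10-fold cross-validated tree-count selection) fits the transformed
   EC50 response to the mixed-type traits plus eigenvectors. Trees handle
   ordered and unordered categoricals natively and route missing values
   without imputation.
4. **Deviance partition** — relative-influence variable importance (VI,
   split-gain totals scaled to sum to 100) is summed by group, so the
   model's percent deviance explained *T* splits into absolute shares
   *T × VI_group / 100* for traits versus phylogeny. Partial-dependence
   curves and a pairwise interaction screen describe the top predictors.

A synthetic-data module (Yule trees, Brownian-motion and Mk trait
simulation, subtype discretisation of a latent response) generates data
with the same structure as the real study — 89 species, 17 typed traits,
13 subtypes — so the whole pipeline and its recovery properties are
exercisable without any downloads.

## A worked example

```r
library(phylobrt)

report <- run_pipeline(pipeline_config(sim = sim_config(), seed = 1))
report
#> <analysis_report>
#> Deviance partition (cv): total 62.9%
#>   trait       56.8% of model deviance =  35.7% of response
#>   phylogeny   43.2% of model deviance =  27.2% of response
#>   eigenvectors retained: 38 (cumulative fraction 0.9908)
#>   top predictors:
#>     incubation_period         32.3% (trait)
#>     EV9                        9.9% (phylogeny)
#>     fledge_period              7.6% (trait)
#>     EV7                        4.9% (phylogeny)
#>     EV3                        4.4% (phylogeny)
#>     lifespan                   4.0% (trait)
```

Reading this: the cross-validated BRT explains 62.9% of the deviance in
the (synthetic) sensitivity response; summing VI scores by group, traits
carry 56.8% and the phylogenetic eigenvectors 43.2% of the model
deviance, i.e. 35.7 and 27.2 percentage points of the response deviance.
The default generator gives its first continuous trait (named
`incubation_period` in the emulated schema) the largest effect, and it is
recovered as the top predictor. `autoplot(report)` draws the VI bar
chart (entries with VI ≥ 0.5%), `plot_partial_dependence(report$pd)` the
top predictors' partial-dependence panels, and `write_report(report, dir)`
writes the report JSON, CSV tables and consensus Newick.

The pieces compose individually — `read_newick_trees()`,
`majority_rule_consensus()`, `patristic_distance_matrix()`,
`phylo_pcoa()`, `select_eigenvectors()`, `build_response()`,
`build_model_frame()`, `fit_brt()` (with `tidy()`/`glance()` methods),
`variable_importance()`, `partial_dependence()`, `interaction_table()`,
`deviance_partition()` — and a thin CLI (`exec/phylobrt`) exposes the
common stages (`simulate`, `consensus`, `distances`, `pcoa`, `run`).

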