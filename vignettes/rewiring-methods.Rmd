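---
title: "Trait-based interaction niches and rewiring potential: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based interaction niches and rewiring potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichewire)
library(dplyr)
```

## The scientific problem

Global change rewires ecological networks: pairwise interactions are lost,
new ones emerge, and the identity of the species providing a function (say,
pollination) turns over. How well a network can absorb this turnover depends
not on the interactions we happen to observe locally, but on the
*fundamental interaction niche* of each species — the full set of partners
it could match functionally, whether or not they currently co-occur.

`nichewire` implements a complete pipeline for quantifying this functional
resilience in bipartite resource–consumer systems (the motivating system is
flower-visiting: plants and nectar-feeding birds):

1. **Metanetwork prediction.** A boosted-regression-tree classifier learns
   the probability that a resource–consumer pair interacts from both
   species' functional traits (plus taxonomic groups as proxies for
   unmeasured traits), trained on pooled site networks with inferred
   absences. Applying it to *every* regional pair gives the probabilistic
   metanetwork, pruned to binary feasibility at a probability threshold
   (default 0.4).
2. **Niche geometry.** Each species' *rewiring capacity* is the functional
   richness (FRic) of its predicted partners: the volume of the convex hull
   those partners span in the partner level's trait space, standardized by
   the hull of all partner-level species, so 1 means "this species can use
   the full functional spectrum of its partner level".
3. **Rewiring potential maps.** For each grid cell and trophic level, the
   partner sets of all locally present focal-level species are pooled
   (partners taken from the metanetwork, *not* filtered by local
   occurrence) and the standardized FRic of the pool is the cell's
   *rewiring potential*. Joint terciles of potential and richness give a
   3×3 bivariate class for co-mapping.
4. **Richness decomposition.** A GAM with a richness smooth (k = 10) and a
   bivariate spatial smooth of the cell centroids separates the richness
   effect on potential from residual spatial structure.

A synthetic-ecosystem generator with a known feasibility kernel makes every
stage testable against ground truth without any external data.

## The synthetic ecosystem generator

The generator (`synth_config()`, `simulate_ecosystem()`) emulates the data
a network compilation provides: two trait tables, site networks with
imperfect detection, and species occurrences on a 0.5° grid.

**Feasibility kernel.** For resource $i$ and consumer $j$,

$$
p_{ij} \;=\; p_{\max}\,
\exp\!\left\{-\frac{(\mathrm{corolla}_i-\mathrm{bill}_j)^2}{2\sigma_j^2}\right\}
\bigl(1-\delta_{\mathrm{cat}}\,
\mathbf{1}[\mathrm{colour\ mismatch}]\bigr).
$$

This is the minimal kernel expressing trait matching: a Gaussian in the
matching-trait difference, a per-consumer tolerance $\sigma_j$ setting
niche breadth, and a single categorical penalty. Defaults: $p_{\max}=0.9$,
$\delta_{\mathrm{cat}}=0.3$ (a colour mismatch reduces but does not forbid
the interaction), and $\sigma_j$ marginally log-normal with
$\mathrm{meanlog}=\log 3$, $\mathrm{sdlog}=0.6$ (millimetres, like the
matching traits).

**Tolerance is allometric by design.** $\log\sigma_j$ is a linear function
of the consumer's standardized log body mass. This is an ecologically
motivated choice (larger consumers tend to be less selective), but it is
also a structural requirement: if tolerance were latent noise, *no*
trait-based model could predict per-consumer niche breadth, and
parameter-recovery tests of the fitted pipeline would be impossible by
construction. Body mass is therefore a matching trait (the tolerance
carrier); `wing_index`, `plant_height` and `nectar_concentration` are
deliberately inert so that variable-importance checks have known negatives.

**Trait scales.** Corolla length is log-normal(2.5, 0.4) and bill length
log-normal(2.5, 0.2): consumer optima sit more centrally than the corolla
spread, so differences in tolerance — not optimum placement or
colour-preference luck — dominate true niche breadth. Under the defaults
the Spearman correlation between $\sigma_j$ and true niche breadth is
around 0.9 at 40 consumers.

**Geography and sampling.** Species ranges are disks with uniform
1–4° radii around uniform centroids on a 20 × 20 grid of 0.5° cells; every
species keeps at least its centroid cell. Study sites are grid cells
sampled without replacement among cells occupied at both levels, which
keeps site communities consistent with the ranges used later for the
potential maps. At a site, each co-occurring pair is observed interacting
with probability $p_{ij}\,p_{\mathrm{detect}}$ ($p_{\mathrm{detect}} =
0.8$), giving roughly 700–950 labelled pairs over the default 30 sites —
deliberately much sparser than a real compilation (which yields hundreds
of labelled pairs per network), but dense enough for the interaction model
to be estimable. A single detection probability is a simplification; real
compilations have heterogeneous effort across studies.

**What passing tests do not show.** The generator has no phylogenetic
trait correlation, no abundance effects, no environmental filtering of
interactions, and ranges are geometric disks. Recovery results on this
substrate demonstrate the pipeline's internal correctness, not the
adequacy of trait matching for any particular empirical system.

**Reproducibility.** One run seed; each stage (traits, truth, ranges,
networks) draws from a sub-stream at a fixed offset, so stages re-run in
isolation reproduce the full-run artifacts bit for bit.

## From site networks to training data

`assemble_training_pairs()` pools networks at the pair level: a pair is a
presence if observed interacting in at least one site, an inferred absence
if it co-occurred somewhere and was never observed interacting, and is
excluded if it never co-occurs. Pooling to pair level matches the target
of inference (the regional metanetwork); whether per-site absences should
be weighted individually is an open modelling question, and the pooling
rule is the package's documented choice.

Missing traits are filled by taxon-group mean (numeric) or mode
(categorical, ties to the lexicographically smallest level), with a global
fallback; every filled cell is flagged. This replaces phylogenetic
ancestral-state imputation — which needs external phylogenies — while
keeping `taxon_group` in the feature set as the taxonomic proxy.

## The interaction model

`fit_link_model()` fits a stochastic gradient-boosted tree ensemble
(binary log-loss) with conventional ecology settings: learning rate 0.01,
interaction depth 3, bag fraction 0.5, up to 5,000 trees. The tree count is
chosen by 5-fold label-stratified internal cross-validation with early
stopping (50 rounds patience) and the ensemble is then refit on all rows;
at the few-hundred-pair scale this is markedly more stable than a single
held-out split. Categorical features use integer codes whose mapping is
stored in the model bundle, so the all-pairs prediction grid is encoded
identically to the training data, and any schema drift is a hard error.

`cross_validate()` reports pooled out-of-fold metrics (AUC, PR-AUC,
accuracy, Cohen's κ, MCC) with label-stratified folds — at ~30% prevalence,
unstratified folds are unstable at small n. Because it is ambiguous which
of 0.4 or 0.5 a given study used as the confusion threshold, metrics are
reported at both. The classification rule is strictly `score > τ`, and
PR-AUC uses step (average-precision) interpolation, since linear
interpolation in PR space is biased.

`choose_threshold()` offers the fixed default τ = 0.4 plus max-κ and
max-Youden grid searches (0.01–0.99, ties to the smallest τ) for
sensitivity analyses.

## Niche geometry

Mixed numeric/categorical traits force an ordination before a hull can be
taken, so FRic is computed in the standard way: Gower dissimilarity
(`cluster::daisy`; range-normalized numeric differences, 0/1 categorical
mismatches, unweighted mean) → square-root correction → principal
coordinates → convex hull on the retained axes.

Numerical conventions, all tested:

* Eigenvalues count as positive above `1e-10 ×` the largest; a warning is
  raised if the residual negative mass exceeds 5% after the square-root
  correction, and axes are truncated.
* One trait space per trophic level, `m_max = 4` axes by default; *every*
  hull at that level uses the same axes, so volumes are comparable across
  species and cells. This trades per-set dimensional fidelity for
  cross-species comparability.
* Member sets that cannot support an m-dimensional hull (≤ m members, or
  affinely dependent) get FRic 0 with a degeneracy flag, rather than a
  lower-dimensional volume: a single standardized scale never mixes
  dimensionalities. Species sets smaller than the trait dimensionality are
  a real occurrence (isolated or near-isolated species), and 0 is the
  package's documented convention for them.
* Constant traits are dropped (with a warning) before Gower, whose range
  term they would make undefined.

The hull volume itself is computed exactly by an incremental
(beneath-beyond) convex-hull construction implemented in the package,
covering any dimension (in practice m ≤ 4; m = 1 uses the range). It is
validated against analytic volumes (squares, simplices, cross-polytopes),
the 2-D shoelace formula, exact monotonicity under point addition, and a
10⁶-draw rejection-sampling Monte-Carlo oracle whose point-in-hull test is
scipy's Delaunay triangulation — an entirely independent code path.

Standardization divides by the hull of **all** partner-level species. This
makes 1 interpretable ("spans the full partner trait space") and gives the
exact dominance guarantee that a cell's potential is at least the capacity
of every local focal-level species (the pool contains each species'
partner set, and hulls are monotone). Dividing by the maximum observed
capacity instead is available (`standardize = "max_capacity"`) and
recorded in the output's metadata, but forfeits that guarantee.

## Rewiring potential maps

`potential_map()` evaluates every cell × level: richness, pooled partner
set, standardized FRic of the pool, and the 3×3 bivariate class. Cells
with no focal-level species get `NA` (distinct from "species present but
functionally narrow", which is 0); pools never filter partners by local
occurrence unless `local_partners = TRUE` is requested for sensitivity
analysis. Tercile breaks use the non-NA cells of each level, with ties
assigned to the lower bin — deterministic and consistent with rank-based
break conventions. Identical pooled partner sets across cells are
detected and their hull computed once, which keeps the map loop fast on
grids where potential saturates.

## The GAM decomposition

`fit_potential_gam()` regresses cell potential on `s(richness, k = 10) +
s(lon, lat, k = 30)` (thin-plate splines, Gaussian identity family, GCV
smoothness selection with REML available; both recorded in the fit).
Potential lives on [0, 1], so a logit-link or beta family is a sensible
sensitivity option — supply `family` — but the default mirrors standard
practice for this response. Smooth p-values are reported without
multiple-testing correction: the two trophic levels are two independent
models.

`partial_effect()` returns the centered richness smooth with pointwise
standard errors and extrapolation flags. Two numerical caveats, both
visible in the tests: with *exactly* zero residual variance the GCV (and
REML) objective is degenerate in the smoothing parameter, so the linear
recovery check adds negligible jitter (σ = 10⁻⁴ on a 0–1 response); and
the selected effective df on (near-)linear truth is itself a random
variable across noise realizations — about a quarter of designs give
edf ≈ 2–3 under any standard selector, which is a property of smoothness
selection, not of this implementation. For curves with sharp curvature
relative to the k = 10 basis (half-saturation below ~5% of the richness
range), the spline can overshoot; recovery tests use half-saturation
constants the basis can represent (8–15 cells over a 0–100/0–200 richness
range), stated here as the package's validation conditions.

## Validation problem sizes

The test-suite and acceptance-script problem sizes are the package's
documented validation conditions: 60 resources × 40 consumers, 20 × 20
grid, 30 sites for pipeline recovery (Spearman ρ between true tolerance
and estimated capacity ≈ 0.85–0.93 across seeds); 5,000 permuted-label
pairs for the null AUC check; 500 cells for GAM recovery; 100 random
instances per exact monotonicity property; 10⁶ Monte-Carlo draws for the
hull oracle.

## A worked miniature

```{r pipeline, eval = FALSE}
eco <- simulate_ecosystem(synth_config(seed = 1))
pairs <- assemble_training_pairs(eco$networks)
fit <- fit_link_model(pairs, eco$resource, eco$consumer, seed = 1)
web <- prune_metaweb(predict_metaweb(fit, eco$resource, eco$consumer), 0.4)

rspace <- trait_space(eco$resource)
cspace <- trait_space(eco$consumer)
capacity <- rewiring_capacity(web, "consumer", rspace)
map <- potential_map(eco$occurrences, web, rspace, cspace)
gam_fit <- fit_potential_gam(map, "resource")

plot_capacity(dplyr::bind_rows(capacity,
                               rewiring_capacity(web, "resource", cspace)))
plot_potential_map(map)
autoplot(gam_fit)
```

## Known limitations

* Interaction-strength (non-topological) rewiring is out of scope; the
  pipeline is purely presence/absence.
* The metanetwork model ignores phylogenetic non-independence beyond the
  taxon-group proxies.
* FRic is the only niche metric implemented; abundance-weighted
  alternatives (dispersion, evenness, kernel hypervolumes) are not.
* Range-polygon rasterisation is out of scope: users supply the
  species-by-cell occurrence table.
* Dense all-pairs storage is deliberate; it is comfortable up to a few
  hundred thousand pairs, which covers regional pools of ~1,000 × ~300
  species.
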