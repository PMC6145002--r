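---
title: "Stacked ensemble niche models and diversity change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble niche models and diversity change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmdiv)
```

## What the package computes

`enmdiv` implements a complete stacked species-distribution-modelling
workflow for assessing how climate change is expected to reorganise the
alpha and beta diversity of an assemblage:

1. **Covariate screening.** Environmental layers are filtered for
   collinearity by iteratively removing the variable with the largest
   variance inflation factor until all VIFs are strictly below 10
   (`select_variables()`).
2. **Per-species niche models.** For each species, presences plus uniform
   background cells are split 80/20 (stratified), and four algorithm
   families are fitted on the training part: a binomial GLM with
   linear-plus-quadratic terms, boosted regression trees, a random forest,
   and a radial-kernel SVM with calibrated probabilities (`enm_fit()`).
   Each model is evaluated on the held-out 20% by the rank-based AUC and by
   the true skill statistic at the sensitivity–specificity equality
   threshold; models with AUC < 0.75 or TSS < 0.3 are excluded as no better
   than chance (`enm_evaluate()`).
3. **Ensembles and ranges.** Passing members are averaged cell-wise — four
   algorithms for the baseline, algorithms × circulation models × emission
   pathways for each future slice (`ensemble_mean()`) — and binarised at the
   mean of the passing members' equality thresholds
   (`consensus_threshold()`, `binarize()`). Projected ranges then pass a
   dispersal filter: an isolated future patch is deleted when it neither
   overlaps the baseline range nor lies within 400 km of the main predicted
   area or of any occurrence record (`dispersal_filter()`).
4. **Diversity metrics.** Binary ranges are stacked on a coarse analysis
   grid (50 km cells on the 10 km modelling raster; union rule). Per-slice
   summaries are: species richness and its per-site change with a paired
   *t* test; local contributions to beta diversity (LCBD) from the Jaccard
   dissimilarity matrix, with a permutation test; and the
   replacement/nestedness decomposition of Jaccard dissimilarity with
   ternary-plot coordinates and centroid.

A virtual-species simulator supplies ground truth so the whole chain can be
validated without any external data.

## The statistical core

**LCBD.** For sites with Jaccard dissimilarities $D = [d_{ij}]$, let
$A = -\tfrac12 D \circ D$ and $G = H A H$ with the centring matrix
$H = I - \mathbf{1}\mathbf{1}^\top/n$. Then

$$\mathrm{SS}_{\mathrm{total}} = \mathrm{tr}(G) = \frac{1}{n}\sum_{i<j} d_{ij}^2,
\qquad \mathrm{BD}_{\mathrm{total}} = \frac{\mathrm{SS}_{\mathrm{total}}}{n-1},
\qquad \mathrm{LCBD}_i = \frac{G_{ii}}{\mathrm{SS}_{\mathrm{total}}}.$$

The LCBD values sum to one; both the trace identity and the sum-to-one
constraint are enforced in the test suite at $10^{-10}$ and $10^{-12}$
respectively. One subtlety: plain Jaccard dissimilarities are not
Euclidean-embeddable, so the centred diagonal can dip marginally below zero
on pathological matrices (observed magnitudes below 0.01). Square-rooting
$D$ first would restore exact non-negativity but would change what
$\mathrm{SS}_{\mathrm{total}}$ measures; the package keeps the direct
formulation and documents the slack. The permutation null shuffles every species column
independently across sites (species independent of one another), and
p-values use the add-one Monte-Carlo estimator so they are never zero.
Permutations that produce an undefined Jaccard pair (two empty sites) or a
zero total sum of squares are skipped and counted. Significance is mapped at
raw $p < 0.05$ by default; a Holm correction can be applied by the user but
is deliberately not the default.

**Replacement/nestedness.** For a site pair with $a$ shared species and
$b, c$ species unique to either site, the Jaccard dissimilarity
$D = (b+c)/(a+b+c)$ splits into

$$\mathrm{Repl} = \frac{2\min(b,c)}{a + 2\min(b,c)}, \qquad
\mathrm{Nes} = D - \mathrm{Repl}, \qquad S = 1 - D,$$

a triplet $(S, \mathrm{Repl}, \mathrm{Nes})$ that is non-negative and sums
to one, plotted in a triangle with vertices Repl $=(0,0)$, Nes $=(1,0)$,
S $=(1/2, \sqrt3/2)$. Pairs where one site is a strict subset of the other
have $\min(b,c)=0$ and therefore pure nestedness.

**Model metrics.** AUC is the Mann–Whitney rank estimator (ties count one
half), identical to brute-force concordant-pair counting. The equality
threshold scans the sorted unique scores plus their midpoints and picks the
candidate minimising $|\text{sens} - \text{spec}|$, breaking ties by larger
TSS and then by the smaller threshold; presence is predicted at scores at or
above the threshold.

## The synthetic study system

The generator emulates the ingredients of a macroecological modelling study
on a planar 10 km grid (distances are Euclidean in km):

- **Climate.** Each covariate is a Gaussian random field — white noise
  smoothed with a Gaussian kernel of standard deviation
  `autocorr_length_km` (default 50 km) — standardized to mean 0, sd 1.
  Future climates add a pathway-scaled trend plus a smooth perturbation
  specific to each pseudo circulation model (sd `gcm_noise_sd`, default
  0.25), the synthetic analogue of a GCM × RCP scenario roster. Default
  roster: slices 2050 (trend × 1.0) and 2070 (× 1.6), pathways ×0.4 (mild)
  and ×1.0 (severe), two circulation models.
- **Species.** A virtual species has a Gaussian-product niche: suitability
  is $\prod_l \exp(-(v_l - \mu_l)^2 / 2\sigma_l^2)$ over the layers, the
  simplest smooth unimodal response. Its *true range* is the set of cells
  with suitability at or above an occupancy threshold (default 0.3).
  Community simulation draws optima at the climate values of random cells
  and breadths uniform on 0.5–1.5 sd.
- **Occurrences.** Presences are drawn without replacement (so duplicate
  records cannot occur) with probability proportional to suitability
  *within the occupied range*. Sampling only where the species actually
  occurs is deliberate: records of a real species come from occupied sites,
  and an estimator calibrated on presences from the full suitability
  surface would systematically overpredict the thresholded range. An
  optional bias field supports sensitivity studies of uneven recording
  effort; it is off by default because its effect on the models is an open
  empirical question, not part of the standard design.
- **Feasibility constraint.** Because the standard design samples 200
  presence cells per species without replacement, the community simulator
  redraws any candidate species whose true range has fewer than
  `min_range_cells` (default 250) cells. This mirrors the rare-species
  filter from the other side: species too narrow to yield the required
  sample would be dropped anyway.

What the generator does **not** emulate: real bioclimatic variable
semantics, geographic coordinate systems (real-data use would require
haversine distances), spatially autocorrelated recording effort, biotic
interactions, and dispersal dynamics beyond the distance-cutoff rule.
Passing recovery tests therefore demonstrates the internal consistency of
the estimation chain, not the realism of any particular ecological claim.

## Numerical and design choices

- **VIF** is computed from per-column OLS $R^2$ (with intercept);
  perfectly collinear columns get `Inf` rather than an error. Removal ties
  go to the first variable in input order; a VIF exactly at the threshold is
  removed ("strictly below" reading). The regressions use all raster cells,
  with a seeded subsample above $10^5$ cells, recorded in the report.
- **GLM concavity.** Quadratic logit terms with positive fitted
  coefficients are dropped (largest first, refitting) until the response is
  concave in every covariate. An unconstrained convex quadratic explodes
  when projected onto climates outside the calibration range — the classic
  extrapolation artifact — and a niche response should be unimodal or
  monotone.
- **Hyperparameters are fixed, not tuned**, mirroring a standardized
  treatment across hundreds of species: BRT depth 3, learning rate 0.1, 100
  rounds; RF 500 trees; SVM radial kernel with default width heuristic and
  Platt scaling; all seeded, single-threaded, deterministic.
- **Background** defaults to 1000 uniform non-presence cells per species;
  the count is recorded in the configuration rather than hidden.
- **Thresholding** of future projections reuses each species' baseline
  consensus threshold: evaluation data exist only for the baseline.
- **Connectivity** is 8-neighbour (diagonal adjacency counts as continuous
  area), configurable in principle via `label_patches()`. Patch distances
  are minimum cell-centre to cell-centre, i.e. edge-to-edge at cell
  resolution; a patch at exactly the 400 km cutoff is retained because the
  rule deletes only patches *more than* 400 km away. The "main predicted
  area" is the largest connected component of the future mask — the only
  reading that makes distance-to-main well defined. The filter is fully
  rule-based; a per-patch removal log supports manual review instead of ad
  hoc manual edits, for reproducibility.
- **Empty sites** are kept as zeros in richness maps but excluded from
  dissimilarity matrices (Jaccard is undefined for two empty sites); the
  exclusions are recorded per slice. If an extreme scenario leaves all
  surviving sites identical, beta diversity is reported as undefined for
  that slice rather than invented.
- **Seeds** fan out from one master seed through a deterministic hash
  (`derive_seed()`), so per-species, per-algorithm and per-permutation
  streams are independent of execution order.

## Scenario constructors for mechanism tests

Two idealised scenarios isolate the beta-diversity mechanisms that climate
change is expected to drive:

- `contract_ranges()` imposes *graded* range loss: a spatial stress
  gradient removes species from cells, with stress tolerance increasing
  with range size, so narrow-ranged specialists disappear first and
  stressed cells retain nested subsets of richer communities. This raises
  the nestedness share of the decomposition centroid. (Uniform random
  thinning does **not** have this property — it pushes pairs toward
  disjointness, which is pure replacement — so the nestedness response is a
  statement about spatially structured loss, not about any contraction.)
- `expand_ranges()` dilates every range, a pure expansion that homogenises
  composition and lowers total beta diversity.

## Problem sizes and validation

The standard validated design is 20 virtual species on a 40×40 grid of
10 km cells (64 coarse sites), 200 presences and 1000 background points per
species, four algorithms, and a 2 × 2 scenario roster per future slice. At
these sizes the full pipeline runs in about a minute on one CPU, and the
test suite verifies: exact LCBD and decomposition identities; permutation
null calibration near the nominal 5% level (199 permutations per test, 30 ×
40 iid matrices); AUC/TSS against brute-force oracles; the VIF filter
against an independent re-implementation; Spearman rank recovery of true
coarse-cell richness above 0.9 in every time slice; loss detection for a
planted cold-edge specialist under severe warming; and the 399/400/401 km
boundary behaviour of the dispersal rule.

## Known limitations

- Per-species evaluation uses a single random 80/20 split, not spatial
  cross-validation; reported AUC/TSS are optimistic where records are
  spatially clustered.
- Presence/background modelling estimates relative, not absolute,
  occurrence probability; binarisation leans on the equality threshold
  being stable across algorithms.
- The dispersal rule is a distance cutoff, not a mechanistic dispersal
  model.
- Real-data mode expects the user to supply curated occurrence tables and
  climate grids; no downloading or taxonomic reconciliation is provided.
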