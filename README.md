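# enmdiv

Stacked ensemble niche models and climate-change diversity metrics.

`enmdiv` is for macroecologists who want to go from per-species occurrence
records and climate grids to assemblage-level answers: how will species
richness gradients shift under future climate scenarios, where do sites
with unique composition (high beta diversity) move, and does climate change
restructure beta diversity toward species replacement or toward nestedness?
The package implements the full chain — collinearity screening, multi-
algorithm niche models, ensemble forecasts across circulation models and
emission pathways, thresholding and dispersal filtering, and alpha/beta
diversity summaries — together with a virtual-species simulator that
provides known truth for validating every stage.

## The statistics at the core

- **Model skill:** rank-based AUC and the true skill statistic
  TSS = sensitivity + specificity − 1, evaluated on a held-out 20% at the
  sensitivity–specificity equality threshold; models with AUC < 0.75 or
  TSS < 0.3 are excluded from ensembles.
- **Local contribution to beta diversity (LCBD):** from the Jaccard
  dissimilarity matrix D, with A = −D∘D/2 and G = HAH (H the centring
  matrix), SS_total = tr(G) = (1/n)Σ_{i<j} d²_ij, BD_total =
  SS_total/(n−1), and LCBD_i = G_ii/SS_total, tested against a permutation
  null in which species are shuffled independently across sites.
- **Beta-diversity partition:** for each site pair with shared count a and
  unique counts b, c, the Jaccard dissimilarity D = (b+c)/(a+b+c) splits
  into replacement Repl = 2·min(b,c)/(a+2·min(b,c)) and nestedness
  Nes = D − Repl; triplets (S, Repl, Nes) with S = 1 − D sum to one and are
  summarised by their ternary-plot centroid.
- **Dispersal rule:** a projected range patch is kept iff it overlaps the
  baseline range, or lies within 400 km of the main (largest) predicted
  area, or within 400 km of any occurrence record.

## Worked example

```r
library(enmdiv)

run <- run_pipeline(pipeline_config(seed = 42, n_perm = 199))
print(run)
```

```
enmdiv run: 20 species on a 40x40 grid (10 km cells), seed 42
variables retained by VIF < 10: env1, env2, env3
mean evaluation metrics by algorithm:
 algorithm   auc   tss
       brt 0.908 0.688
       glm 0.915 0.714
        rf 0.908 0.687
       svm 0.897 0.671
species passing in >= 1 algorithm: 20 of 20
2050: 0 species with no suitable area; BDtotal 0.2912 (baseline 0.2486)
2070: 0 species with no suitable area; BDtotal 0.3204 (baseline 0.2486)
richness recovery (Spearman vs truth): baseline 0.980, 2050 0.948, 2070 0.935
```

The run simulates three autocorrelated climate layers and 20 virtual
species, samples 200 presence cells per species, fits GLM/BRT/RF/SVM models
per species, ensembles the passing members across 2 pseudo circulation
models × 2 emission pathways for 2050 and 2070, binarises at the consensus
threshold, applies the 400 km dispersal filter, and aggregates ranges onto
a 50 km grid (64 sites). The printed block shows: per-algorithm mean AUC
and TSS on held-out data (all comfortably above the 0.75/0.3 exclusion
cutoffs), the count of species predicted to lose all suitable area per
slice, total beta diversity per slice (rising dissimilarity here: ranges
shift and shrink under the warming trend), and the Spearman correlation
between stacked predicted richness and the simulator's true richness per
coarse cell — the headline recovery check, above 0.9 in every slice.

Per-site results live in the returned object (`run$richness`,
`run$beta$baseline$lcbd`, `run$beta[["2070"]]$triplets`, ...), and
`render_outputs(run, "out/")` writes the CSV tables plus richness, gain/
loss, LCBD and ternary figures.

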