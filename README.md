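# enmpipe

Ensemble environmental niche modeling (ENM / species distribution modeling)
for climate-change range forecasting, built as a tested, reusable R
pipeline. It is aimed at ecologists who model habitat for
mountain-dwelling species — the reference use case is a high-elevation
ungulate in a Pamir-like landscape — and who want the full published
protocol, from raw occurrence points and environmental rasters to
consensus habitat maps and stable/gain/loss change accounting, in
reproducible, scriptable form.

## What it computes

Given presence points and gridded predictors (bioclim-style climate layers
plus DEM-derived terrain metrics), the pipeline:

1. thins occurrences to one per pixel and splits them 70/30 into
   training/testing sets;
2. samples pseudo-absence ("background") points inside the 95% minimum
   convex polygon of the presences;
3. prunes collinear predictors (drops one of each pair with Pearson
   r > 0.7, guided by an explicit priority ranking);
4. fits five presence/background model families behind one contract —
   stepwise logistic GLM, MARS, boosted regression trees, random forest,
   and a Maxent-style penalized logistic model;
5. binarizes each model's suitability surface at its
   sensitivity = specificity threshold (fitted on training scores, then
   frozen) and evaluates test-split AUC, the true skill statistic
   TSS = sensitivity + specificity − 1, and percent correctly classified;
6. sums the binary maps into an agreement ensemble and keeps cells where
   ≥ 3 of 5 models agree (the present consensus map);
7. projects to future climate scenarios (GCM × RCP × horizon), requiring
   ≥ 3 models within each GCM and ≥ 2 of 4 GCMs to call a future cell
   suitable;
8. classifies change per cell — (present, future) = (1,1) stable, (0,1)
   gain, (1,0) loss, (0,0) unsuitable — and reports km² (latitude-aware
   pixel areas) and percentages of the present suitable area, per scenario
   and averaged across RCPs.

A synthetic-landscape module generates a mountainous DEM (3,300–7,300 m),
elevation-coupled climate layers, a riparian network, pseudo-GCM scenario
deltas, and a virtual species with known truth, so the entire pipeline is
testable end to end without any external data. See the vignette
(`vignettes/ensemble-niche-modeling.Rmd`) for the models, parameters, and
design rationale.

## Worked example

```r
library(enmpipe)

config <- pipeline_config(
  landscape = landscape_config(nrow = 80, ncol = 80, seed = 42),
  n_occurrences = 400, n_background = 1200,
  hyper = list(brt = list(max_trees = 300, cv_folds = 5)),
  seed = 42)
result <- run_pipeline(config)

result$evaluation_table
result$change_table
```

which prints (compact 80 × 80 demo landscape):

```
        family       auc auc_class       tss percent_correct threshold
1 glm_stepwise 0.7771100      good 0.4228632        72.19828 0.5194721
2         mars 0.8287660      good 0.4645299        75.43103 0.6668552
3          brt 0.8158520      good 0.4728632        76.07759 0.6641563
4           rf 0.7911592      good 0.4540598        70.90517 0.4912144
5  maxent_like 0.8307158      good 0.4893162        76.29310 0.6538044

      scenario present_km2 stable_km2 stable_pct gain_km2 gain_pct loss_km2 loss_pct
1   rcp45_2050         564        471       83.5      609    108.0       93     16.5
2   rcp85_2050         564        385       68.4      987    175.0      178     31.6
3   rcp45_2070         564        438       77.7      842    149.4      125     22.3
4   rcp85_2070         564        160       28.4     1569    278.4      404     71.6
5 average_2050         564        428       76.0      798    141.5      135     24.0
6 average_2070         564        299       53.1     1206    213.9      265     46.9
```

Read: all five families discriminate the virtual niche (test AUC
0.78–0.83, "good" on the Swets scale; TSS 0.42–0.49). The present 3-of-5
consensus covers 564 km² of this compact demo landscape. Warming shifts
the suitable band upslope: losses grow with forcing (16.5% of the present
suitable area under the moderate pathway at 2050 → 71.6% under the extreme
pathway at 2070) while larger gains open at higher elevations (mean
elevation of gained cells ≈ 4,700–5,000 m vs ≈ 4,100–4,300 m for lost
cells, from `result$scenarios[[id]]$bands`), and the RCP-averaged rows
summarize each horizon.

A thin CLI wrapper over the same functions lives at
`inst/cli/enm-pipeline.R` (`--config config.yaml --seed 1 --outdir out`);
it writes the evaluation and change tables as CSV, all maps as ASCII
grids, the MCP as WKT, and a JSON manifest recording seeds, thresholds,
and retained predictors.

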