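# hexiht

Intratumoral heterogeneity and immune-response indicators from
digital-pathology cell coordinates, with the downstream survival
modeling — for pathologists and image-analysis groups who have per-case
cell tables (one row per detected cell: x/y in μm, tumor/stroma/background
compartment, per-marker positivity) and want prognostic indicators beyond
global positivity percentages.

## What it computes

**Heterogeneity indicators.** The cell point pattern is subsampled by a
randomly positioned hexagonal grid (side 257 μm by default); hexagons
with fewer than 50 cells are discarded. Per-hexagon positivity
percentages are ranked into decile bins, and a symmetric 10×10
co-occurrence matrix *P* over adjacent hexagon pairs yields five
Haralick texture features:

- contrast ∑ (i−j)² P_ij, dissimilarity ∑ |i−j| P_ij,
- entropy −∑ P_ij ln P_ij, energy ∑ P_ij², homogeneity ∑ P_ij/(1+(i−j)²).

Bimodality of the per-hexagon percentage distribution is summarized by
Ashman's D from a two-component Gaussian mixture (EM):

    D = √2 |μ₁ − μ₂| / √(σ₁² + σ₂²)

**Global indicators.** ER/PR/Ki67 percentages and HER2 (2+/3+ classes)
in the tumor compartment; HIF1α percentages and CD8+ / CD8+SATB1+
densities (cells/mm²) per compartment.

**Survival layer.** Optimal cutpoint scanning (minimum log-rank p with
a 10% minimum group fraction, flagged as selection-biased), Kaplan–Meier
and log-rank analysis, multivariable Cox models with Efron ties and
likelihood-ratio statistics, |r| > 0.90 correlation pruning, and
leave-one-out subset-frequency selection.

**Synthetic data.** A generator producing cell maps with controlled
spatial heterogeneity (homogeneous / gradient / hotspot / patchy-mosaic
positivity fields over Poisson cell patterns with exact compartment
geometry) and survival cohorts with planted covariate effects, so the
whole pipeline is testable without patient data.

## Worked example

```r
library(hexiht)

# a synthetic case: patchy PR expression over a 6x6 mm tumor field
map <- generate_cell_map(scenario_spec(
  fields = list(pr = field_patchy(0.15, 0.85, patch_mm = 1.2)), seed = 42))
map
#> <cell_map> case synthetic-case - 90411 cells
#>   bounds (um): 0, 0, 6000, 6000
#>   areas (mm^2): tumor=36.000, stroma=0.000
#>   markers: pr

compute_indicators(map, "pr", seed = 42)[
  , c("percent_global", "entropy", "energy", "ashman_d", "n_hexagons")]
#>  percent_global  entropy    energy ashman_d n_hexagons
#>        51.93395 2.772408 0.1583432 4.299156        237
```

Half the cells are PR-positive overall, but the expression is spatially
split into high- and low-expressing patches: texture entropy 2.77 (a
homogeneous map of the same 52% positivity scores ≈ 1.4) and Ashman's
D 4.3 (clearly bimodal; homogeneous maps score below ~1.3). 237
hexagons passed the 50-cell filter.

```r
# a synthetic 101-case cohort with planted effects: protective
# CD8+SATB1+ tumor density and PR entropy, harmful Ki67 bimodality
res <- run_cohort(list(cohort = list(seed = 42)))
res$lr_comparison
#>          model                                          covariates       lr         lr_p
#> 1 conventional age+grade3+t2+n_pos+er_pct+pr_pct+ki67_pct+her2_pct 10.70010 2.192775e-01
#> 2     extended                  cd8_satb1_d_t+pr_entropy+ki67_ashd 35.37599 1.014588e-07

res$cox_extended
#> <cox_model> n = 101, events = 18, LR = 35.38 on 3 df (p = 1e-07)
#>                        term      beta     hr  lower  upper        p
#> cd8_satb1_d_t cd8_satb1_d_t -0.008757 0.9913 0.9785 1.0040 1.86e-01
#> pr_entropy       pr_entropy -1.216000 0.2963 0.1607 0.5463 9.75e-05
#> ki67_ashd         ki67_ashd  0.391700 1.4790 1.2180 1.7970 7.73e-05
```

The extended model (the three novel indicators) recovers the planted
directions — hazard ratios below 1 for CD8+SATB1+ density and PR
entropy, above 1 for Ki67 bimodality — and carries far more
likelihood-ratio power (35.4 on 3 df) than the conventional
clinicopathological + global-IHC model (10.7 on 8 df) on the same
cases. `res$cutoffs` holds the per-indicator optimal cutpoints with
their (selection-biased) log-rank p-values.

Real data enter through `read_cell_table()` (CSV/TSV with a
configurable column mapping, plus a compartment-area sidecar) and
`run_cohort(list(indicators = ..., survival = ...))`.

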