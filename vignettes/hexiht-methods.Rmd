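---
title: "Methods: hexagonal-grid heterogeneity indicators and survival modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hexagonal-grid heterogeneity indicators and survival modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Digital image analysis of immunohistochemistry (IHC) slides yields, per
case, a table of detected cells: micrometer coordinates, a tissue
compartment (tumor / stroma / background), and positivity flags for
markers such as ER, PR, Ki67, HER2 (as a 0/1+/2+/3+ staining class),
CD8, SATB1 and HIF1α. Conventional reporting reduces this to global
expression percentages. hexiht additionally quantifies *where* the
positive cells sit — the intratumoral heterogeneity of expression — and
carries all indicators into survival models. The package targets
hormone receptor-positive breast carcinoma cohorts, where heterogeneity
indicators of PR and Ki67 and the density of CD8+SATB1+
tumor-infiltrating lymphocytes have been reported as independent
predictors of overall survival, but nothing in the code is specific to
that disease.

# From cells to heterogeneity indicators

## Hexagonal subsampling

The cell point pattern is subsampled by a randomly positioned grid of
regular, pointy-top hexagons with side length $s$ (default
$s = 257\,\mu m$, hexagon area $\tfrac{3\sqrt 3}{2} s^2 \approx
0.172\,mm^2$). The random offset is drawn uniformly over one lattice
period, so grid placement introduces no alignment with tissue
structures; one placement is used per case and marker, with the seed
recorded in the output. Cells are assigned to hexagons by the inverse
affine map to fractional axial coordinates followed by cube rounding —
exactly nearest-center assignment, since the hexagons are the Voronoi
cells of their centers. Boundary ties resolve deterministically through
the rounding rule.

Within each hexagon the positive and negative cells of the chosen
marker (tumor compartment by default) are counted. Hexagons with fewer
than 50 cells are discarded as insufficient sampling; discarded
hexagons also do not contribute adjacency, so they break co-occurrence
chains. Orientation is fixed to pointy-top: the statistics are
rotation-insensitive in expectation and a fixed choice keeps runs
reproducible.

## Co-occurrence matrix and Haralick features

Per-hexagon positivity percentages are ranked into ten fixed intervals
(bin 1 is $[0, 10]$, bin $k$ is $(10(k{-}1), 10k]$). For every
unordered pair of adjacent retained hexagons (the 6-neighborhood,
axial distance 1) with bins $(a, b)$, equal mass is added at $(a,b)$
and $(b,a)$; normalizing gives a symmetric $10 \times 10$ co-occurrence
matrix $P$. Five standard grey-level co-occurrence features summarize
it:

* contrast $\sum_{ij} (i-j)^2 P_{ij}$ and dissimilarity
  $\sum_{ij} |i-j| P_{ij}$ — local gradient magnitude;
* entropy $-\sum_{ij} P_{ij}\ln P_{ij}$ — disorder (natural log,
  $0\ln 0 := 0$; bounded by $\ln 100$ on this support);
* energy $\sum_{ij} P_{ij}^2$ (angular second moment) and homogeneity
  $\sum_{ij} P_{ij} / (1 + (i-j)^2)$ (inverse difference moment) —
  uniformity.

The feature names are used in several non-equivalent ways across the
texture literature; the definitions above are the canonical GLCM ones,
and any monotone variant would stratify cases identically downstream,
because the survival layer only uses cutpoints on the indicator scale.
Only unordered adjacent pairs at distance 1 enter the matrix; no
directional displacements are used, as the tissue has no preferred
axis.

## Ashman's D bimodality

The distribution of the retained per-hexagon percentages is summarized
by Ashman's D: a two-component Gaussian mixture is fitted and

$$D = \sqrt{2}\,\frac{|\mu_1 - \mu_2|}{\sqrt{\sigma_1^2 + \sigma_2^2}}.$$

$D$ grows when expression splits into spatially coherent high- and
low-expressing populations; $D \gtrsim 2$ indicates a genuinely
bimodal split. The mixture is fitted by EM on the raw percentage
values (not a binned histogram) with:

* 5 restarts — the first initialized at the 25%/75% sample quantiles,
  the rest randomly perturbed — keeping the best log-likelihood;
* convergence when the log-likelihood changes by less than $10^{-8}$,
  at most 500 iterations;
* a variance floor of $10^{-4}$ (percent$^2$);
* a minimum mixing weight of 0.05, renormalized at each M-step.

The weight floor needs a word. The likelihood of a Gaussian mixture is
unbounded: a component can collapse onto two or three outlying
hexagons with near-zero variance, and such spurious maxima inflate $D$
for perfectly unimodal inputs (we observed unimodal maps scoring above
bimodal ones through exactly this route). Requiring each component to
carry at least 5% of the hexagons is the mixture-level analogue of the
50-cell hexagon filter: a spatial expression mode supported by a
handful of sampling units is noise, not structure. With the floor in
place, equal-mean mixtures score $D < 1$ and the closed-form case
$0.5\,N(20, 5^2) + 0.5\,N(80, 5^2)$ is recovered at $D \approx 12$
within a few percent at realistic sample sizes.

Indicators are undefined — reported as missing, never as zero — when
fewer than 10 hexagons survive filtering (Ashman's D) or no adjacent
retained pair exists (the texture features); `compute_indicators()`
attaches a reason code.

# Global indicators

Global percentages are positive / evaluated cells within a compartment;
cells lacking a marker flag are excluded from that marker's denominator
(markers are stained on different serial sections, so absence of a flag
is missingness, not negativity). HER2 counts the 2+ and 3+ staining
classes as positive. Densities (CD8+, CD8+SATB1+) divide matching-cell
counts by the compartment area in mm², which must be supplied
explicitly (in synthetic data it is known exactly from the layout); the
package takes no position on how the upstream classifier measured the
area. Background-compartment cells are retained in files but excluded
from every indicator. Zero evaluable cells make an indicator undefined
(`NA`), which is distinct from 0%.

# The survival layer

* **Kaplan–Meier / log-rank** — product-limit estimation and the
  standard chi-square log-rank test (delegated to the `survival`
  package).
* **Optimal cutpoints** — each indicator is dichotomized at the
  midpoint candidate (between consecutive sorted unique values)
  minimizing the log-rank p-value, subject to both groups holding at
  least 10% of the cases. The returned p-value and hazard ratio are
  flagged `selection_biased`: the scan optimizes over many splits and
  no multiplicity correction is applied, matching common practice with
  cutpoint-finding tools. Ties in p resolve toward the smallest
  cutoff.
* **Cox models** — partial likelihood with the Efron tie
  approximation; per-covariate log-hazards, hazard ratios with 95%
  Wald intervals, and the model likelihood-ratio statistic against the
  null. Non-convergence or separation raises an error naming the
  covariate rather than returning unstable estimates.
* **Correlation pruning** — indicators are walked in a user-supplied
  priority order and dropped when $|r| > 0.90$ against any
  already-retained indicator; the priority order (conventional markers
  first, by convention) decides which member of a correlated pair
  survives.
* **Leave-one-out subset frequency** — in each leave-one-out fold,
  forward selection on the Cox partial likelihood (entry at
  likelihood-ratio $p < 0.05$) picks a covariate subset; subsets are
  tallied across folds. Forward selection was chosen over backward
  elimination because candidate sets can exceed what ~24 events
  support as a full starting model. With a small cohort this
  frequency table, not any single fit, is the stable evidence for a
  final model.
* **PR stratification** — the arch-shaped relation between PR% and PR
  entropy motivates three groups: low (< 20%), moderate (20–80%,
  inclusive), high (> 80%).
* An optional Benjamini–Hochberg flag adjusts the Cox covariate
  p-values and the cutoff-table p-values per family. Note BH cannot
  repair the selection bias of scanned cutpoints; on null cohorts the
  adjusted Cox family behaves at the nominal rate while scanned
  cutoff p-values remain anti-conservative.

`run_case()` and `run_cohort()` compose the stages from one
configuration (R list or YAML) and write CSV tables plus a JSON
provenance sidecar carrying all seeds, the grid parameters and a config
hash.

# The synthetic-data generator

The generator emulates the *tabular export* of the upstream image
analysis — never the image. Defaults describe one plausible tissue:

| parameter | default | why |
|---|---|---|
| tissue extent | 6 × 6 mm | desk-scale stand-in for full-face excision sections; yields ~240 hexagons, enough that mixture fits are not noise-dominated |
| tumor cell intensity | 2500 cells/mm² | typical carcinoma cellularity; ~430 cells per hexagon, comfortably above the 50-cell filter |
| stroma cell intensity | 1500 cells/mm² | sparser than tumor |
| hexagon side | 257 μm | the analysis default, kept in sync |
| patchy mosaic scale | 0.6 mm (`field_patchy`) | hexagon-commensurate tiles; for strongly bimodal maps use 1–1.5 mm so tiles cover several hexagons |

Cells are a homogeneous Poisson pattern per compartment (`whole` layout:
all tumor; `blobs`: non-overlapping circular tumor nests in stroma, so
compartment areas are exact). Marker positivity is Bernoulli with a
spatially structured probability field: homogeneous, linear gradient,
hotspots, or a patchy random mosaic (Voronoi tessellation of a coarse
Poisson process, tiles assigned probability $p_1$ or $p_2$). The mosaic
directly plants the hexagon-scale bimodality Ashman's D targets; tiles
much larger than a hexagon give clean bimodality, hexagon-scale tiles
give many straddling hexagons and hence high texture entropy.
`positivity_sweep()` uses symmetric tiles around a target mean to trace
the entropy-versus-positivity arch: entropy is zero when every hexagon
sits in the same decile bin (expression near 0% or 100%) and maximal in
the 20–80% range.

Survival cohorts draw covariates from pluggable generators (defaults:
plausible marginals for the global percentages and clinicopathological
variables, an arch-shaped PR entropy given PR%, gamma-distributed Ki67
bimodality, log-normal CD8+SATB1+ density) and survival times from a
proportional-hazards model with planted per-unit log-hazards on
mean-centered covariates and an exponential (or Weibull) baseline,
administratively censored. Cohort defaults are fixed to the study
conditions this package mirrors: 101 cases, censoring at 143 months,
and baseline rate 0.0013/month, calibrated once so that roughly 24% of
cases die within follow-up; the planted effects are protective
CD8+SATB1+ density and PR entropy and harmful Ki67 bimodality, at
about 0.6–0.75 per covariate standard deviation — deliberately more
moderate than published dichotomized hazard ratios, which exaggerate
per-SD effects.

What passing tests on these data do **not** show: real slides have
segmentation errors, staining artifacts, irregular tissue boundaries,
anisotropic and non-Poisson cell arrangements, and correlated marker
fields across serial sections. The generator validates the statistical
machinery — count conservation, estimator calibration, direction and
power of planted effects — not the biology of any cohort.

# Numerical choices and degenerate inputs

* Decile bin edges are closed on the right; 10.0 is bin 1, 10.5 is
  bin 2. Values outside $[0, 100]$ are errors, not clamped.
* Hexagon boundary points resolve by cube rounding (deterministic).
* The EM is run on percentages in $[0, 100]$; with zero sample
  variance the fit degenerates to two identical components and $D = 0$.
* The cutoff scan requires at least two distinct indicator values and
  one admissible split; otherwise it returns an undefined result with
  a reason, as do all heterogeneity indicators, rather than a zero.
* Coordinates are written at 17 significant digits so a write/read
  round trip reproduces doubles exactly.
* Seeds: every stochastic stage takes or records an explicit seed;
  `run_case()` derives per-marker seeds from the configured seed.

# Problem sizes in the shipped tests

The test-suite simulations are sized for minutes, not hours: maps of
up to 6 × 6 mm (~90,000 cells), 20-replicate map contrasts, 200
replicate Cox recoveries at n = 1000, 1000-replicate log-rank
calibration at n = 100, and 100 replicate cohorts at the study scale
(n = 101). The same properties hold at larger sizes with tighter
Monte-Carlo error.

# Known limitations

* Single grid placement per case; averaging indicators over several
  placements would reduce placement noise at proportional cost.
* The co-occurrence construction treats all discarded hexagons as
  adjacency breaks; sparse tissue can fragment the lattice and leave
  few pairs.
* The cutoff scan's selection bias is reported, not corrected;
  permutation-based correction would be the natural extension.
* Compartment areas must come from upstream; the package does not
  estimate tissue area from the point pattern.
* No competing risks, time-varying covariates, or
  proportional-hazards diagnostics.
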