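Package: hexiht
Title: Hexagonal-Grid Intratumoral Heterogeneity Indicators and Survival
    Modeling for Digital Pathology Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes prognostic indicators from cell-coordinate tables
    exported by digital image analysis of immunohistochemistry slides:
    global biomarker positivity percentages, immune-cell densities, and
    intratumoral heterogeneity statistics obtained by subsampling the cell
    point pattern with a randomly positioned hexagonal grid (Haralick
    texture features of a decile co-occurrence matrix and Ashman's D
    bimodality from a two-component Gaussian mixture). Includes the
    downstream survival layer (optimal cutpoint scanning, Kaplan-Meier and
    log-rank analysis, multivariable Cox regression, correlation pruning,
    leave-one-out subset-frequency selection) and a synthetic-data
    generator producing cell maps with controlled spatial heterogeneity
    and survival cohorts with planted covariate effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
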