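Package: morphowrap
Title: Grid-Cast 3D Morphometrics for Landmark-Poor Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scan-extract-wrap-compute workflow for comparing 3D surface
    morphologies of organisms that offer few anatomical landmarks. Intensity
    stacks (multi-page TIFF) or triangulated meshes are turned into casts of
    homologously indexed surface points by projecting a warped 2D template
    grid onto the surface (shrink-wrapping). Casts are superimposed by
    partial or full Procrustes fit, and localised group differences are
    quantified by displacement heat maps, dense point-wise Wilcoxon rank-sum
    test fields with Storey q-value false discovery rate control, and a
    95 percent confidence-ellipsoid overlap statistic validated by label
    permutation. A synthetic half-body generator with known group effects
    supports end-to-end validation without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
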