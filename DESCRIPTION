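Package: ostium
Title: Outlet Flow Splitting and Hemodynamic Metrics for Intracranial Aneurysm Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing outlet boundary-condition flow-splitting
    strategies in cerebrovascular flow analysis and for quantifying
    aneurysmal hemodynamics. Implements Murray-law flow splitting (exponents
    n = 2 and n = 3), hierarchical per-bifurcation splitting on circular and
    raytraced anatomical cross-sections, and a zero-pressure surrogate based
    on a 0D Poiseuille resistance network; a metric suite for time-resolved
    velocity and wall-shear-stress fields (vorticity, kinetic energy and its
    sac-to-parent ratio, oscillatory velocity index, TAWSS, normalized TAWSS,
    low shear area); and variability statistics for segmentation ensembles
    (deviation-versus-reference tables, scaled-MAD outlier exclusion,
    relative-deviation reduction summaries). Ships a synthetic-data module
    generating bifurcating vessel trees, segmentation ensembles and analytic
    pulsatile flow phantoms with known metric values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
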