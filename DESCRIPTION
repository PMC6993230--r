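Package: perivasc
Title: Perivascular Penetration Profiling of Nanocarriers from Multichannel
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how far nanocarriers penetrate beyond the blood
    vessel lumen into brain parenchyma after blood-brain-barrier
    sonopermeation. Segments the vasculature from a vessel-marker channel,
    computes exact anisotropy-aware Euclidean distance maps, bins tissue
    into concentric 5 micrometre perivascular shells in 2D and 3D, and
    reports per-compartment penetration profiles, carrier-positive area
    fractions, extravasation- and IgG-positive vessel classifications,
    percent-injected-dose conversions, and the accompanying group
    statistics (t-tests and two-way ANOVA with Bonferroni-corrected
    per-compartment comparisons). Includes a seeded synthetic phantom
    generator with exactly known ground truth for validating every stage
    of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    tiff,
    xml2,
    yaml,
    jsonlite,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
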