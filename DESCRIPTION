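Package: coverwise
Title: Training-Sample Cover Stratification for Hyperspectral Mapping of
    Invasive and Expansive Herbs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates hyperspectral scenes in which an invasive or
    expansive herbaceous species occurs at known percentage cover, builds
    cover-stratified reference-polygon designs, classifies the target
    species with a Random Forest on Minimum Noise Fraction (MNF)
    components, and evaluates the resulting presence-absence maps with a
    three-criteria scheme: Kappa and F1 on held-out polygons,
    per-cover-stratum true-positive fractions, and zonal confusion against
    field-mapped truth patches in a control area. Implements the full
    sampling-design experiment (Stage 0 random split, Stage 1 cover-range
    scenarios SC0-SC4, Stage 2 training-set sizes 20/30/40) as a
    reproducible, seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
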