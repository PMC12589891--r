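Package: cartprofiler
Title: Multiparametric Potency Profiling of CAR T Cell Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native toolkit for multiparametric characterisation of
    chimeric antigen receptor (CAR) T cell products. Covers high-dimensional
    spectral flow cytometry analysis (arcsinh scaling, drift cleaning,
    subsampling, self-organizing-map clustering with average-linkage
    metaclustering, min-max cluster profiling, boolean gating signatures),
    image-based serial tumor-killing assays (per-round normalised percent
    killing and 3-day/33-day integrated-value scores), composite radar-chart
    potency scorecards with z-scaled polygon areas, post-treatment correlate
    analysis (cytokine group scores, timepoint deltas, Spearman association,
    trapezoidal persistence AUC, Pearson regression), and panel-establishment
    quality control (stain index, titration selection, FMO variability). A
    synthetic-data module generates study-shaped inputs with known ground
    truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    EBImage,
    stringr
Config/testthat/edition: 3
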