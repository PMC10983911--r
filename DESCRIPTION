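Package: voxrel
Title: Test-Retest Reliability of Repeated-Measures 3D Brain Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies test-retest reliability of repeated-measures 3D
    statistical brain maps at the individual level (voxelwise and
    region-of-interest intraclass correlations with variance components and
    F-statistic confidence bounds) and at the group level (Jaccard and Dice
    similarity of thresholded maps, Spearman correlation of continuous maps).
    Includes precision-weighted fixed-effects combination of run-level
    estimates, contrast design efficiency, multiverse-style decision grids
    with specification-curve summaries, bootstrap sample-size stability
    curves, and a synthetic-data generator with known ground-truth variance
    components so every analysis is testable end-to-end without real imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
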