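Package: assembloidq
Title: Quantification of Tumor Infiltration, Migration, and Therapy
    Response in Assembloid Imaging Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Boundary-referenced quantification of tumor-cell infiltration
    into neural organoids from multichannel fluorescence stacks: exact
    point-in-polygon and distance-to-boundary geometry, concentric-shell
    intensity profiling, eGFP/DAPI infiltration metrics, marker-to-DAPI
    ratios normalized to untreated controls, per-cell infiltration
    distances from detected marker-positive centroids, 2D spheroid
    migration scoring, four-parameter logistic dose-response fitting,
    and one-/two-way ANOVA with Dunnett and Tukey multiple-comparison
    families. Includes a synthetic-scene generator with known ground
    truth (boundary polygon, cell depths, marker effects, IC50) for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    emmeans,
    optparse,
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
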