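Package: socialfly
Title: Quantifying Social Feeding Behavior and Comparative Expression in Fly Chamber Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fly aggregation and social spacing from
    chamber video frames and for comparing group-feeding behavior across
    Drosophila species. Detects flies in arena images by thresholding and
    moment-based ellipse fitting, computes aggregation kinetics (T-40
    time-to-threshold), the cooperativity coefficient (slope of T-40 on fly
    density), body-size-normalized social space from nearest-neighbor
    distances, and Z-score relative positioning of paint-marked flies.
    Includes an agent-based cooperative food-search simulator, a
    comparative-transcriptome stage (TPM renormalization, Spearman/Ward
    expression clustering, consensus differential-expression calling,
    permutation tests of gene-set overlap), and a synthetic-data generator
    that produces ground-truth-annotated chamber frames, aggregation time
    series, and orthologous expression matrices for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
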