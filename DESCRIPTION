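Package: isoscreen
Title: Isoform-Specific Activity Profiling and Virtual Screening of
    Carbonic Anhydrase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A machine-learning toolkit for isoform-specific profiling of
    human carbonic anhydrase (hCA) inhibitors. Curates Ki bioactivity
    tables into labeled, deduplicated, stratified train/test sets;
    featurizes standardized structures with four molecular representations
    (2048-bit circular and path fingerprints, an 881-bit substructure-key
    fingerprint, and a physicochemical descriptor vector); trains and
    evaluates SVM, random-forest, k-nearest-neighbour and Gaussian-process
    classifiers, including Tanimoto-kernel variants; runs a multi-stage
    virtual-screening cascade (probability cutoff, PAINS and structural
    alerts, Lipinski/Veber rules, novelty filtering, cross-isoform
    profiling); and explains predictions with permutation Shapley values
    retro-mapped from fingerprint bits to atoms. A synthetic-data
    generator provides fully reproducible fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    kernlab,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
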