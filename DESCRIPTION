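Package: metsys
Title: Systems-Level Analysis of Metabolic Disease with Microbiome,
    Immune, Diet, and Metabolome Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for systems-level analysis of metabolic
    disease in multi-omic cohort studies.  Builds a composite metabolic
    disease score from fasting blood markers (log-transformed, shifted
    first principal component) with a clinically anchored impairment
    cutoff; detects co-occurring microbial and dietary feature modules
    with a compositionality-aware SparCC correlation estimator and
    shared-minimum-distance subtree clustering; selects predictive
    features by three-phase random-forest variable selection with a
    permutation null for out-of-bag variance explained; extracts
    feature-feature interactions from iterated, importance-weighted
    forests; constructs FDR-thresholded Spearman association networks;
    attributes plasma metabolites to the gut microbiome by gene-reaction
    producibility and germfree-versus-colonized differential abundance;
    and fits age-adjusted rank-based (Wilcoxon score) regressions.  A
    synthetic cohort generator emulates every data layer with planted,
    recoverable structure so the full pipeline is testable without
    access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    randomForest,
    ranger,
    rpart,
    vegan,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
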