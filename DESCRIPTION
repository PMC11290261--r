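Package: mgpflux
Title: Prediction of Metabolite-Gene-Pathway Sets from Metabolic Models and Tumor Omics
Version: 0.1.0
Authors@R:
    person("MGP", "Maintainers", email = "maintainers@mgpflux.org", role = c("aut", "cre"))
Description: Implements a four-step constraint-based workflow that predicts
    metabolite-gene-pathway sets (MGPs): metabolites and biosynthetic pathways
    whose production differs significantly between tumor samples carrying a
    somatic mutation and wild-type samples. Per-sample intracellular fluxes are
    fitted to RNA-seq expression by least-absolute-deviation linear programming
    on a genome-scale metabolic model, metabolite turnover is summarized as
    flux-sums with a pathway decomposition, and mutation-stratified Wilcoxon
    tests plus a modified Z-score outlier rule select the final MGPs. Also
    provides the cohort preprocessing used around the workflow: a somatic
    mutation filter cascade, metabolome peak filtering, k-nearest-neighbor
    imputation, generalized-log normalization, ROC-AUC validation statistics,
    and seeded synthetic fixtures (toy metabolic models and simulated cohorts)
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    limma,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
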