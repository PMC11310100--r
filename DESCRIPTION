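Package: rehomics
Title: Multi-Scale Regional Homogeneity Classification and
    Transcriptome-Neuroimaging Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying local synchronization of resting-state
    BOLD signal at multiple spatial scales and its molecular correlates.
    Implements Kendall's-W regional homogeneity (ReHo) maps with residual
    nuisance preprocessing (Friston-24 motion expansion, spike regression
    at a framewise-displacement threshold, band-pass filtering),
    hierarchical parcellation aggregation, support-vector-machine
    case-control classification with F-score feature selection and
    permutation inference, Allen-atlas-style microarray probe processing
    (background filtering, RNA-seq concordance, representative probes,
    differential stability), signed weighted co-expression network
    modules with eigengenes, spatial correlation of module eigengenes
    with covariate-adjusted case-control difference maps, and a local
    hypergeometric over-representation analysis. A seeded synthetic-data
    generator emulates the cohort and expression bundle with planted
    effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    e1071,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    nortest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
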