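Package: MorphoRates
Title: Branch-Wise Morphological Rates on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tracing morphological diversification through time
    from 2-D landmark and semi-landmark data on a dated phylogeny. Reads
    TPS landmark files and time-calibrated Newick/Nexus trees, resamples
    outlines to equally spaced semi-landmarks, superimposes configurations
    by generalized Procrustes analysis, ordinates shapes by principal
    component and canonical variate analysis with confusion-matrix
    classification, reconstructs ancestral landmark configurations by
    branch-length-weighted squared-change parsimony and ancestral discrete
    states by parsimony or an equal-rates Markov model, and computes
    per-branch deformation ratios (morphological distance per million
    years) together with along-lineage sequential growth rates. A
    simulation module generates tree-structured shape data with known
    Brownian-motion rates so every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    MASS,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
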