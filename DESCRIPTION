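Package: ToxConsensus
Title: Consensus Machine-Learning Toxicity Classification with Atom-Level
    Shapley Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An offline toolkit for binary toxicity prediction of small
    molecules from SMILES. Compounds are encoded with three fingerprint
    families (Morgan circular, RDKit path-based topological, and an
    881-bit PubChem-layout substructure-key fingerprint), classified with
    four algorithm families (random forest, support vector machine,
    k-nearest neighbour, multilayer perceptron) tuned by grid search
    under repeated random-split cross-validation scored by the Matthews
    correlation coefficient, and combined through an exhaustive consensus
    scan over all model subsets. Predictions are explained with Kernel
    SHAP feature attributions that are retro-mapped from fingerprint bits
    onto atoms, yielding signed per-atom weights that highlight candidate
    toxicophores on the structure. Molecule handling (parsing,
    canonicalization, substructure matching, depiction) is delegated to
    the RDKit Python library through a batch subprocess bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    FNN,
    quadprog,
    optparse,
    Rcpp
LinkingTo: Rcpp
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python'
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
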