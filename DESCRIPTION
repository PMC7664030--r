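Package: qsmart
Title: Explainable Multi-Omics Modeling of Protein Kinase Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts log-IC50 drug response of cancer cell lines to protein
    kinase inhibitors from drug substructure fingerprints and seven levels of
    multi-omics cell-line features (residue, motif, domain, gene, family,
    pathway, sample). Candidate product-interaction terms (drug-by-mutation,
    expression-weighted protein-protein interactions, and pairwise
    reaction/pathway/Gene Ontology perturbation counts) are screened
    individually by nested-model F-tests under false-discovery-rate control,
    the design matrix is reduced by prioritized variance-inflation-factor
    screening and Lasso with Bayesian Information Criterion model selection,
    and the response surface is fit by small feed-forward neural networks
    sized by the geometric pyramid rule under 10-fold cross-validation with
    L1 regularization. Explanation utilities report unit-perturbation effect
    attributions, drug-mutation interaction analyses, and signed
    protein-protein-interaction edge impacts. A synthetic-data generator with
    planted effects supports end-to-end validation without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
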