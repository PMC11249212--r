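Package: lymphrep
Title: B Cell Receptor Repertoire Metrics and Lymphoma Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing immunoglobulin heavy-chain (IGH) B cell
    receptor repertoires from clonotype tables in the AIRR Rearrangement
    dialect, and for classifying lymphoma subtypes (NLPBL, DLBCL, CLL)
    against healthy-donor repertoires with interpretable machine-learning
    models. Provides record-level filtering and clonotype collapsing,
    repertoire metrics (clonality as one minus Pielou's evenness, Shannon
    diversity in bits, richness, somatic-hypermutation fraction at the 98
    percent germline-identity threshold), fixed-length top-n clonotype
    featurization with Kidera-factor CDR3 descriptors and one-hot VDJ gene
    usage, stratified train/test splitting with random oversampling and
    stratified k-fold grid-search cross-validation over multinomial ridge
    logistic regression and random forests, and an interpretation layer
    (PCA embedding with MANOVA, coefficient-magnitude predictor ranking).
    A synthetic cohort generator with class-specific clonal-dominance
    presets allows the whole pipeline to run and be validated without
    access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    ranger,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
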