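Package: cpifuse
Title: Compound-Protein Interaction Prediction with Kronecker Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Y-shaped neural architecture for compound-protein interaction
    (CPI) modelling: attributed molecular graphs built from SMILES (78-bit
    atom features), pluggable per-residue protein sequence embeddings
    (one-hot, k-mer, or pretrained language-model caches), a GraphSAGE or
    GCN compound encoder, a variable-length recurrent (LSTM/GRU/RNN) protein
    encoder, Kronecker-product feature fusion, and a two-layer prediction
    head for binding-affinity (pIC50) regression or binary interaction
    classification. Includes a seeded training engine with early stopping
    and checkpoint ensembling, rigorous split schemes (random, cold-protein,
    cold-compound, blind), regression and classification metric suites
    (MSE, Pearson, rm2, AUC, AUPR), a fine-tuning workflow for assessing
    drug selectivity across closely related targets, and a seeded synthetic
    benchmark generator with planted effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
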