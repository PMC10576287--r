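# Shared fixtures for the test suite. Heavy objects (the synthetic study
# dataset and the pretrained model) are computed once per session, on first
# use, under fixed seeds.

.study <- new.env(parent = emptyenv())

study_backend <- function() embedding_backend("kmer")

# small Y-shaped model matching the desk-scale study conditions
study_model <- function(task = "regression", input_width = study_backend()$width,
                        dropout = 0.2, seed = 3L) {
  cpi_model(task,
            compound = compound_encoder_config("graphsage", n_layers = 3L,
                                               hidden = 32L, out_dim = 16L),
            protein = protein_encoder_config("lstm", hidden = 16L,
                                             input_width = input_width),
            fusion = "kronecker_pair", head_hidden = 64L, dropout = dropout,
            seed = seed)
}

# 500-pair regression benchmark (10 proteins in families x 50 compounds)
study_data <- function() {
  if (is.null(.study$data)) {
    syn <- generate_synthetic(synthetic_spec(seed = 11L))
    .study$syn <- syn
    .study$data <- build_dataset(syn$pairs, study_backend())
  }
  .study$data
}

# fixed hidden/train/val partition of the study data (hidden = held out)
study_split <- function() {
  data <- study_data()
  with_seed_t(101L, {
    n <- nrow(data$pairs)
    hid <- sample(n, round(0.2 * n))
    vis <- setdiff(seq_len(n), hid)
    val <- sample(vis, 40L)
    list(hidden = hid, val = val, train = setdiff(vis, val))
  })
}

# from-scratch training run on the visible share; doubles as the pretrained
# model for the transfer/selectivity tests
study_pretrain <- function() {
  if (is.null(.study$pretrain)) {
    data <- study_data()
    sp <- study_split()
    .study$pretrain <- train_cpi(
      study_model(), subset_dataset(data, sp$train),
      subset_dataset(data, sp$val),
      train_config(batch_size = 32L, lr = 3e-3, max_epochs = 200L,
                   patience = 15L, seed = 5L))
  }
  .study$pretrain
}

# seed helper local to tests (the package's with_seed is internal)
with_seed_t <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# hand-built molecular_graph with arbitrary feature width (for closed-form
# encoder checks)
toy_graph <- function(features, edges) {
  structure(list(node_features = features,
                 edges = matrix(as.integer(edges), ncol = 2L),
                 smiles = "toy", canonical = "toy",
                 atom_count = nrow(features), elements = NULL,
                 feature_width = ncol(features)),
            class = "molecular_graph")
}

toy_embedding <- function(mat, backend_id = "toy") {
  structure(list(matrix = mat, L = nrow(mat), h = ncol(mat),
                 backend_id = backend_id, sequence_hash = "toy",
                 truncated = FALSE),
            class = "residue_embedding")
}

# permute the atoms of a molecular graph: node i of the input becomes
# node perm[i] of the output
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g2 <- g
  g2$node_features <- g$node_features[inv, , drop = FALSE]
  if (nrow(g$edges)) {
    e <- cbind(perm[g$edges[, 1L]], perm[g$edges[, 2L]])
    g2$edges <- matrix(as.integer(t(apply(e, 1L, sort))), ncol = 2L)
  }
  g2
}
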