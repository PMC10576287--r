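#' Compound encoder configuration
#'
#' @param arch `"graphsage"` (mean aggregator over the full neighbourhood)
#'   or `"gcn"` (symmetric degree-normalized convolution with self-loops).
#' @param n_layers Number of message-passing layers (default 3).
#' @param hidden Hidden width of each layer.
#' @param out_dim Output width d_c after mean pooling + linear map.
#' @param feature_width Width of the atom feature vectors (78 under the
#'   default [feature_scheme()]).
#' @return A `"compound_encoder_config"`.
#' @export
compound_encoder_config <- function(arch = c("graphsage", "gcn"),
                                    n_layers = 3L, hidden = 128L,
                                    out_dim = 128L, feature_width = 78L) {
  arch <- match.arg(arch)
  stopifnot(n_layers >= 1L, hidden >= 1L, out_dim >= 1L)
  structure(list(arch = arch, n_layers = as.integer(n_layers),
                 hidden = as.integer(hidden), out_dim = as.integer(out_dim),
                 feature_width = as.integer(feature_width)),
            class = "compound_encoder_config")
}

#' Protein encoder configuration
#'
#' @param cell Recurrent cell: `"lstm"` (default), `"gru"` or `"rnn"`.
#' @param hidden Hidden width d_p; the encoder output is the arithmetic
#'   mean of the per-residue hidden states.
#' @param input_width Embedding width h of the chosen backend.
#' @return A `"protein_encoder_config"`.
#' @export
protein_encoder_config <- function(cell = c("lstm", "gru", "rnn"),
                                   hidden = 128L, input_width = 21L) {
  cell <- match.arg(cell)
  stopifnot(hidden >= 1L, input_width >= 1L)
  structure(list(cell = cell, hidden = as.integer(hidden),
                 input_width = as.integer(input_width)),
            class = "protein_encoder_config")
}

#' Joint representation width of a fusion mode
#'
#' `concat` gives d_p + d_c; `kronecker_pair` gives (d_p+1)(d_c+1) (each
#' branch is augmented with a trailing 1 so original features survive in
#' the product); `kronecker_triple` additionally multiplies by the
#' augmented concatenation, giving (d_p+1)(d_c+1)(d_p+d_c+1).
#'
#' @param mode Fusion mode.
#' @param d_p,d_c Branch widths.
#' @return Integer joint width.
#' @export
joint_width <- function(mode = c("kronecker_pair", "concat",
                                 "kronecker_triple"), d_p, d_c) {
  mode <- match.arg(mode)
  switch(mode,
         concat = d_p + d_c,
         kronecker_pair = (d_p + 1L) * (d_c + 1L),
         kronecker_triple = (d_p + 1L) * (d_c + 1L) * (d_p + d_c + 1L))
}

# columnwise per-row Kronecker product: column (i-1)*nb+j = Ha[,i]*Hb[,j]
kron_cols <- function(Ha, Hb) {
  na <- ncol(Ha); nb <- ncol(Hb)
  Ha[, rep(seq_len(na), each = nb), drop = FALSE] *
    Hb[, rep(seq_len(nb), times = na), drop = FALSE]
}

kron_cols_backward <- function(Ha, Hb, dK) {
  na <- ncol(Ha); nb <- ncol(Hb)
  Sa <- Matrix::kronecker(Matrix::Diagonal(na), Matrix::Matrix(1, nb, 1))
  Sb <- Matrix::kronecker(Matrix::Matrix(1, na, 1), Matrix::Diagonal(nb))
  list(dHa = as.matrix((dK * Hb[, rep(seq_len(nb), times = na),
                                drop = FALSE]) %*% Sa),
       dHb = as.matrix((dK * Ha[, rep(seq_len(na), each = nb),
                                drop = FALSE]) %*% Sb))
}

aug1 <- function(H) cbind(H, 1)

fusion_forward <- function(Hp, Hc, mode) {
  if (mode == "concat") {
    return(list(HK = cbind(Hp, Hc), cache = list(mode = mode,
                                                 dp = ncol(Hp),
                                                 dc = ncol(Hc))))
  }
  Hpa <- aug1(Hp); Hca <- aug1(Hc)
  HK2 <- kron_cols(Hpa, Hca)
  if (mode == "kronecker_pair")
    return(list(HK = HK2, cache = list(mode = mode, Hpa = Hpa, Hca = Hca)))
  Hm <- aug1(cbind(Hc, Hp))
  HK <- kron_cols(HK2, Hm)
  list(HK = HK, cache = list(mode = mode, Hpa = Hpa, Hca = Hca, HK2 = HK2,
                             Hm = Hm, dc = ncol(Hc), dp = ncol(Hp)))
}

fusion_backward <- function(cache, dHK) {
  mode <- cache$mode
  if (mode == "concat") {
    return(list(dHp = dHK[, seq_len(cache$dp), drop = FALSE],
                dHc = dHK[, cache$dp + seq_len(cache$dc), drop = FALSE]))
  }
  if (mode == "kronecker_triple") {
    bk <- kron_cols_backward(cache$HK2, cache$Hm, dHK)
    dHK2 <- bk$dHa
    dHm <- bk$dHb
    dc <- cache$dc; dp <- cache$dp
    extra_c <- dHm[, seq_len(dc), drop = FALSE]
    extra_p <- dHm[, dc + seq_len(dp), drop = FALSE]
  } else {
    dHK2 <- dHK
    extra_c <- extra_p <- 0
  }
  bk2 <- kron_cols_backward(cache$Hpa, cache$Hca, dHK2)
  dp <- ncol(cache$Hpa) - 1L
  dc <- ncol(cache$Hca) - 1L
  list(dHp = bk2$dHa[, seq_len(dp), drop = FALSE] + extra_p,
       dHc = bk2$dHb[, seq_len(dc), drop = FALSE] + extra_c)
}

#' Fuse protein and compound representations
#'
#' Standalone form of the joint module for single vectors: each branch is
#' augmented with a trailing 1, then fused per `mode` (see [joint_width()]).
#'
#' @param h_p,h_c Numeric vectors.
#' @param mode Fusion mode.
#' @return Numeric joint vector of length `joint_width(mode, ...)`.
#' @examples
#' fuse(c(0, 0), c(0, 0), "kronecker_pair")  # 9 entries, single 1 at the end
#' @export
fuse <- function(h_p, h_c, mode = c("kronecker_pair", "concat",
                                    "kronecker_triple")) {
  mode <- match.arg(mode)
  out <- fusion_forward(matrix(h_p, 1L), matrix(h_c, 1L), mode)$HK
  stopifnot(ncol(out) == joint_width(mode, length(h_p), length(h_c)))
  drop(out)
}

# recurrent weights: torch-style U(-1/sqrt(d), 1/sqrt(d))
uinit <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

# feed-forward weights: He-uniform, variance-preserving under (Leaky)ReLU;
# keeps encoder outputs O(1) through the stacked layers
he_init <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / fan_in), nr, nc)
}

#' Build a CPI model
#'
#' Constructs the Y-shaped network: a graph encoder for compounds, a
#' recurrent encoder for proteins, Kronecker-product (or concatenation)
#' fusion, and a two-layer LeakyReLU head producing either one real value
#' (pIC50 regression) or two class logits (interaction classification).
#' All weights are initialized uniformly in ±1/sqrt(fan_in) under `seed`.
#'
#' @param task `"regression"` or `"classification"`.
#' @param compound A [compound_encoder_config()].
#' @param protein A [protein_encoder_config()].
#' @param fusion Fusion mode (see [joint_width()]).
#' @param head_hidden Hidden width of the prediction head.
#' @param dropout Dropout rate applied to both encoder outputs and after
#'   the first head layer during training (inactive at inference).
#' @param leaky_slope Negative slope of LeakyReLU.
#' @param seed Integer seed for weight initialization.
#' @return A `"cpi_model"`: list with `config` and `params`.
#' @export
cpi_model <- function(task = c("regression", "classification"),
                      compound = compound_encoder_config(),
                      protein = protein_encoder_config(),
                      fusion = "kronecker_pair", head_hidden = 256L,
                      dropout = 0.2, leaky_slope = 0.01, seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(compound, "compound_encoder_config"),
            inherits(protein, "protein_encoder_config"),
            dropout >= 0, dropout < 1)
  fusion <- match.arg(fusion, c("kronecker_pair", "concat",
                                "kronecker_triple"))
  d_k <- joint_width(fusion, protein$hidden, compound$out_dim)
  out_w <- if (task == "regression") 1L else 2L
  params <- with_seed(seed, {
    d <- protein$hidden
    gm <- rnn_gate_mult(protein$cell)
    prot <- list(Wx = uinit(protein$input_width, gm * d, protein$input_width),
                 Wh = uinit(d, gm * d, d),
                 b = numeric(gm * d))
    layers <- vector("list", compound$n_layers)
    inw <- compound$feature_width
    for (l in seq_len(compound$n_layers)) {
      win <- if (compound$arch == "graphsage") 2L * inw else inw
      layers[[l]] <- list(W = he_init(win, compound$hidden, win),
                          b = numeric(compound$hidden))
      inw <- compound$hidden
    }
    proj <- list(W = he_init(compound$hidden, compound$out_dim,
                             compound$hidden),
                 b = numeric(compound$out_dim))
    head <- list(W1 = he_init(d_k, head_hidden, d_k),
                 b1 = numeric(head_hidden),
                 W2 = he_init(head_hidden, out_w, head_hidden),
                 b2 = numeric(out_w))
    list(prot = prot, comp = list(layers = layers, proj = proj), head = head)
  })
  structure(
    list(config = list(task = task, compound = compound, protein = protein,
                       fusion = fusion, head_hidden = as.integer(head_hidden),
                       joint_width = d_k, dropout = dropout,
                       leaky_slope = leaky_slope, seed = as.integer(seed)),
         params = params),
    class = "cpi_model")
}

#' Number of trainable parameters
#'
#' @param model A [cpi_model()].
#' @return Integer parameter count (a deterministic function of the
#'   configuration alone).
#' @export
n_params <- function(model) {
  cnt <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else cnt <<- cnt + length(x)
    invisible(NULL)
  }
  walk(model$params)
  cnt
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full forward pass over packed batches. train=TRUE draws dropout masks
# from the current RNG stream.
model_forward <- function(model, cbatch, pbatch, train = FALSE) {
  cfg <- model$config
  slope <- cfg$leaky_slope
  cf <- graph_encoder_forward(model$params$comp, cbatch, cfg$compound$arch,
                              slope)
  pf <- rnn_cell_forward(cfg$protein$cell, model$params$prot, pbatch$X,
                         pbatch$mask, pbatch$lens)
  Hc <- cf$Hc
  Hp <- pf$Hp
  rate <- if (train) cfg$dropout else 0
  mc <- dropout_mask(nrow(Hc), ncol(Hc), rate)
  mp <- dropout_mask(nrow(Hp), ncol(Hp), rate)
  if (!is.null(mc)) Hc <- Hc * mc
  if (!is.null(mp)) Hp <- Hp * mp
  ff <- fusion_forward(Hp, Hc, cfg$fusion)
  hd <- model$params$head
  Z1 <- ff$HK %*% hd$W1 + matrix(hd$b1, nrow(ff$HK), length(hd$b1),
                                 byrow = TRUE)
  A1 <- leaky_relu(Z1, slope)
  m1 <- dropout_mask(nrow(A1), ncol(A1), rate)
  D1 <- if (is.null(m1)) A1 else A1 * m1
  Z2 <- D1 %*% hd$W2 + matrix(hd$b2, nrow(D1), length(hd$b2), byrow = TRUE)
  if (cfg$task == "regression") {
    pred <- drop(leaky_relu(Z2, slope))
  } else {
    pred <- softmax_rows(Z2)
  }
  list(pred = pred, Z2 = Z2,
       cache = list(cf = cf$cache, pfc = pf$cache, ff = ff$cache,
                    HK = ff$HK, Z1 = Z1, D1 = D1, mc = mc, mp = mp,
                    m1 = m1))
}

# dZ2: gradient of the loss wrt the head's final pre-activation Z2
# (for regression the caller must already include the output LeakyReLU).
model_backward <- function(model, cache, dZ2) {
  cfg <- model$config
  slope <- cfg$leaky_slope
  hd <- model$params$head
  gW2 <- crossprod(cache$D1, dZ2)
  gb2 <- colSums(dZ2)
  dD1 <- dZ2 %*% t(hd$W2)
  dA1 <- if (is.null(cache$m1)) dD1 else dD1 * cache$m1
  dZ1 <- dA1 * leaky_relu_grad(cache$Z1, slope)
  gW1 <- crossprod(cache$HK, dZ1)
  gb1 <- colSums(dZ1)
  dHK <- dZ1 %*% t(hd$W1)
  fb <- fusion_backward(cache$ff, dHK)
  dHp <- fb$dHp
  dHc <- fb$dHc
  if (!is.null(cache$mp)) dHp <- dHp * cache$mp
  if (!is.null(cache$mc)) dHc <- dHc * cache$mc
  gcomp <- graph_encoder_backward(model$params$comp, cache$cf, dHc)
  gprot <- rnn_cell_backward(model$params$prot, cache$pfc, dHp)
  list(prot = gprot, comp = gcomp,
       head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# loss + gradient wrt Z2 for a labelled batch
batch_loss <- function(model, fwd, labels) {
  n <- nrow(fwd$Z2)
  if (model$config$task == "regression") {
    resid <- fwd$pred - labels
    loss <- mean(resid^2)
    dpred <- 2 * resid / n
    dZ2 <- matrix(dpred * leaky_relu_grad(fwd$Z2[, 1L],
                                          model$config$leaky_slope),
                  n, 1L)
  } else {
    y <- as.integer(labels)  # 0/1
    p <- fwd$pred
    eps <- 1e-12
    loss <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], eps)))
    onehot <- matrix(0, n, 2L)
    onehot[cbind(seq_len(n), y + 1L)] <- 1
    dZ2 <- (p - onehot) / n
  }
  list(loss = loss, dZ2 = dZ2)
}

#' Encode a compound graph to its d_c-dimensional representation
#'
#' Applies the configured message-passing layers, mean-pools the node
#' states and maps them through the output linear layer.
#'
#' @param graph A [smiles_to_graph()] result (or list of them).
#' @param model A [cpi_model()].
#' @return Numeric vector of width `out_dim` (or a matrix, one row per
#'   graph).
#' @export
encode_compound <- function(graph, model) {
  single <- inherits(graph, "molecular_graph")
  graphs <- if (single) list(graph) else graph
  if (!length(graphs))
    stop("encode_compound needs molecular_graph objects with >= 1 atom",
         call. = FALSE)
  for (g in graphs) {
    if (!inherits(g, "molecular_graph") || g$atom_count < 1L)
      stop("encode_compound needs molecular_graph objects with >= 1 atom",
           call. = FALSE)
    if (ncol(g$node_features) != model$config$compound$feature_width)
      stop("graph feature width ", ncol(g$node_features),
           " does not match model feature_width ",
           model$config$compound$feature_width, call. = FALSE)
  }
  out <- graph_encoder_forward(model$params$comp,
                               pack_compound_batch(graphs),
                               model$config$compound$arch,
                               model$config$leaky_slope)$Hc
  if (single) drop(out) else out
}

#' Encode a protein embedding to its d_p-dimensional representation
#'
#' Runs the recurrent cell across residues and returns the arithmetic mean
#' of the per-step hidden states.
#'
#' @param embedding A [embed_sequence()] result (or list of them; batching
#'   pads to the longest sequence but padded steps contribute nothing).
#' @param model A [cpi_model()].
#' @return Numeric vector of width `hidden` (or a matrix).
#' @export
encode_protein <- function(embedding, model) {
  single <- inherits(embedding, "residue_embedding")
  embs <- if (single) list(embedding) else embedding
  for (e in embs) {
    if (e$h != model$config$protein$input_width)
      stop("embedding width ", e$h, " does not match encoder input width ",
           model$config$protein$input_width, call. = FALSE)
    if (e$L < 1L) stop("empty embedding", call. = FALSE)
  }
  pb <- pack_protein_batch(embs)
  out <- rnn_cell_forward(model$config$protein$cell, model$params$prot,
                          pb$X, pb$mask, pb$lens)$Hp
  if (single) drop(out) else out
}

#' Apply the prediction head to a joint vector
#'
#' Two affine layers with LeakyReLU (dropout inactive at inference).
#' Regression returns one real value (pIC50); classification returns the
#' two class probabilities.
#'
#' @param h_K Joint vector (or matrix, one row per pair).
#' @param model A [cpi_model()].
#' @return Numeric prediction(s).
#' @export
predict_head <- function(h_K, model) {
  if (is.null(dim(h_K))) h_K <- matrix(h_K, 1L)
  if (ncol(h_K) != model$config$joint_width)
    stop("joint vector width ", ncol(h_K), " does not match model width ",
         model$config$joint_width, call. = FALSE)
  hd <- model$params$head
  slope <- model$config$leaky_slope
  A1 <- leaky_relu(h_K %*% hd$W1 + matrix(hd$b1, nrow(h_K), length(hd$b1),
                                          byrow = TRUE), slope)
  Z2 <- A1 %*% hd$W2 + matrix(hd$b2, nrow(A1), length(hd$b2), byrow = TRUE)
  if (model$config$task == "regression") drop(leaky_relu(Z2, slope))
  else softmax_rows(Z2)
}

#' @export
print.cpi_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<cpi_model> task=%s  %s(%d layers) + %s  fusion=%s",
                     "  d_K=%d  params=%d\n"),
              cfg$task, cfg$compound$arch, cfg$compound$n_layers,
              cfg$protein$cell, cfg$fusion, cfg$joint_width, n_params(x)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds `config.json` (machine-readable
#' architecture) and `weights.rds`. Loading validates that the weight
#' shapes agree with the configuration.
#'
#' @param model A [cpi_model()].
#' @param dir Checkpoint directory (created if needed).
#' @return `save_model()` the directory, invisibly; `load_model()` the
#'   model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(
    list(task = cfg$task, compound = unclass(cfg$compound),
         protein = unclass(cfg$protein), fusion = cfg$fusion,
         head_hidden = cfg$head_hidden, joint_width = cfg$joint_width,
         dropout = cfg$dropout, leaky_slope = cfg$leaky_slope,
         seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cj <- jsonlite::read_json(file.path(dir, "config.json"),
                            simplifyVector = TRUE)
  model <- cpi_model(
    task = cj$task,
    compound = compound_encoder_config(cj$compound$arch, cj$compound$n_layers,
                                       cj$compound$hidden, cj$compound$out_dim,
                                       cj$compound$feature_width),
    protein = protein_encoder_config(cj$protein$cell, cj$protein$hidden,
                                     cj$protein$input_width),
    fusion = cj$fusion, head_hidden = cj$head_hidden, dropout = cj$dropout,
    leaky_slope = cj$leaky_slope, seed = cj$seed)
  w <- readRDS(file.path(dir, "weights.rds"))
  check_same_shapes(model$params, w)
  model$params <- w
  model
}

check_same_shapes <- function(a, b, path = "") {
  if (is.list(a)) {
    if (!is.list(b) || !identical(names(a), names(b)))
      stop("checkpoint mismatch at ", path, call. = FALSE)
    for (nm in names(a)) check_same_shapes(a[[nm]], b[[nm]],
                                           paste0(path, "$", nm))
    for (i in seq_along(a)) if (is.null(names(a)))
      check_same_shapes(a[[i]], b[[i]], paste0(path, "[[", i, "]]"))
  } else if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("checkpoint weight shape mismatch at ", path, call. = FALSE)
  }
  invisible(TRUE)
}
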