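# Batched molecular-graph encoders (GCN and GraphSAGE) over a block-diagonal
# sparse representation: all graphs of a batch are stacked into one node
# matrix, with per-batch sparse operators for message passing and mean
# pooling. Manual backprop.
#
# GCN layer:        H' = act( D^{-1/2} (A + I) D^{-1/2} H W + b )
# GraphSAGE layer:  H' = act( [H, mean_{u in N(v)} H_u] W + b )
# (mean aggregator over the full neighbourhood; molecular graphs have
# degree <= 4, so no neighbourhood sampling is used)

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

# Stack graphs into one batch structure with sparse operators.
pack_compound_batch <- function(graphs) {
  ns <- vapply(graphs, function(g) g$atom_count, integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  total <- sum(ns)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  ei <- integer(0); ej <- integer(0)
  for (b in seq_along(graphs)) {
    e <- graphs[[b]]$edges
    if (nrow(e)) {
      ei <- c(ei, e[, 1L] + offs[b], e[, 2L] + offs[b])
      ej <- c(ej, e[, 2L] + offs[b], e[, 1L] + offs[b])
    }
  }
  A <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(total, total))
  deg <- Matrix::rowSums(A)
  # GCN operator: sym-normalized adjacency with self loops
  dhalf <- 1 / sqrt(deg + 1)
  Ahat <- Matrix::Diagonal(total, dhalf) %*%
    (A + Matrix::Diagonal(total)) %*% Matrix::Diagonal(total, dhalf)
  # SAGE operator: row-normalized adjacency (zero row for isolated nodes)
  rs <- ifelse(deg > 0, 1 / deg, 0)
  Nmean <- Matrix::Diagonal(total, rs) %*% A
  # mean pooling: B x total
  P <- Matrix::sparseMatrix(i = rep(seq_along(graphs), ns),
                            j = seq_len(total),
                            x = rep(1 / ns, ns),
                            dims = c(length(graphs), total))
  list(X = X, Ahat = Ahat, Nmean = Nmean, P = P, n_graphs = length(graphs))
}

# params: list of layers, each list(W, b), then proj list(W, b)
graph_encoder_forward <- function(params, batch, arch, slope = 0.01) {
  H <- batch$X
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    W <- params$layers[[l]]$W
    b <- params$layers[[l]]$b
    if (arch == "gcn") {
      M <- as.matrix(batch$Ahat %*% H)
    } else {
      M <- cbind(H, as.matrix(batch$Nmean %*% H))
    }
    Z <- M %*% W + matrix(b, nrow(M), length(b), byrow = TRUE)
    caches[[l]] <- list(M = M, Z = Z, Hin = H)
    H <- leaky_relu(Z, slope)
  }
  pooled <- as.matrix(batch$P %*% H)
  Hc <- pooled %*% params$proj$W +
    matrix(params$proj$b, nrow(pooled), length(params$proj$b), byrow = TRUE)
  list(Hc = Hc, cache = list(caches = caches, pooled = pooled, arch = arch,
                             slope = slope, batch = batch))
}

graph_encoder_backward <- function(params, cache, dHc) {
  arch <- cache$arch
  slope <- cache$slope
  batch <- cache$batch
  grads <- list(layers = vector("list", length(params$layers)), proj = NULL)
  grads$proj <- list(W = crossprod(cache$pooled, dHc), b = colSums(dHc))
  dpooled <- dHc %*% t(params$proj$W)
  dH <- as.matrix(Matrix::crossprod(batch$P, dpooled))
  for (l in rev(seq_along(params$layers))) {
    cl <- cache$caches[[l]]
    dZ <- dH * leaky_relu_grad(cl$Z, slope)
    grads$layers[[l]] <- list(W = crossprod(cl$M, dZ), b = colSums(dZ))
    dM <- dZ %*% t(params$layers[[l]]$W)
    if (arch == "gcn") {
      dH <- as.matrix(Matrix::crossprod(batch$Ahat, dM))
    } else {
      nin <- ncol(cl$Hin)
      dH <- dM[, 1:nin, drop = FALSE] +
        as.matrix(Matrix::crossprod(batch$Nmean,
                                    dM[, nin + 1:nin, drop = FALSE]))
    }
  }
  grads
}
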