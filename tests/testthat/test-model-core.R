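# The Y-shaped network: encoders, Kronecker fusion, head, gradients.

ns <- asNamespace("cpifuse")

test_that("joint widths follow the fusion-mode formulas exactly", {
  expect_equal(joint_width("concat", 128, 128), 256)
  expect_equal(joint_width("kronecker_pair", 128, 128), 129 * 129)
  expect_equal(joint_width("kronecker_triple", 1, 1), 2 * 2 * 3)
  m <- cpi_model("regression", seed = 1)
  expect_equal(m$config$joint_width, 16641)
})

test_that("fuse matches brute-force outer products", {
  # all-zero inputs: only the product of the two appended 1s survives
  z <- fuse(c(0, 0), c(0, 0), "kronecker_pair")
  expect_length(z, 9L)
  expect_equal(sum(z), 1)
  expect_equal(z[9], 1)
  # random vectors vs base::kronecker (oracle), d up to 8
  set.seed(4)
  for (d in c(1, 2, 3, 5, 8)) {
    hp <- rnorm(d); hc <- rnorm(d)
    expect_equal(fuse(hp, hc, "kronecker_pair"),
                 as.vector(kronecker(c(hp, 1), c(hc, 1))), tolerance = 1e-12)
    expect_equal(fuse(hp, hc, "concat"), c(hp, hc))
    expect_equal(fuse(hp, hc, "kronecker_triple"),
                 as.vector(kronecker(kronecker(c(hp, 1), c(hc, 1)),
                                     c(hc, hp, 1))), tolerance = 1e-12)
  }
  # triple product at d_p = d_c = 1: all 12 terms enumerated by hand
  a <- 2; b <- 3
  expect_equal(fuse(a, b, "kronecker_triple"),
               c(a * b * b, a * b * a, a * b,
                 a * b, a * a, a,
                 b * b, b * a, b,
                 b, a, 1))
})

test_that("prediction head reproduces hand-computed affine/LeakyReLU values", {
  m <- cpi_model("regression",
                 compound = compound_encoder_config(out_dim = 1, hidden = 2),
                 protein = protein_encoder_config(hidden = 1, input_width = 3),
                 fusion = "concat", head_hidden = 1, seed = 1)
  # zero weights and biases -> 0
  m$params$head <- list(W1 = matrix(0, 2, 1), b1 = 0,
                        W2 = matrix(0, 1, 1), b2 = 0)
  expect_equal(predict_head(c(1, 1), m), 0)
  # identity-like 1x1 path with a negative pre-activation:
  # z1 = -2 -> a1 = -0.02; z2 = -0.02 -> out = -0.0002
  m$params$head <- list(W1 = matrix(c(1, 0), 2, 1), b1 = 0,
                        W2 = matrix(1, 1, 1), b2 = 0)
  expect_equal(predict_head(c(-2, 0), m), -2 * 0.01 * 0.01)
  expect_equal(predict_head(c(3, 0), m), 3)
  expect_error(predict_head(c(1, 2, 3), m), "width")
})

test_that("classification head yields probabilities summing to one", {
  m <- cpi_model("classification",
                 compound = compound_encoder_config(hidden = 4, out_dim = 2),
                 protein = protein_encoder_config(hidden = 2, input_width = 5),
                 head_hidden = 4, seed = 2)
  p <- predict_head(rnorm(m$config$joint_width), m)
  expect_length(p, 2L)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(sum(p), 1)
})

test_that("GCN on a single node reduces to the closed-form limit", {
  # one node, no edges: normalized adjacency is the identity, so each layer
  # is leakyrelu(v W + b) and the output is the linear projection of the
  # final node state
  m <- cpi_model("regression",
                 compound = compound_encoder_config("gcn", n_layers = 2,
                                                    hidden = 4, out_dim = 3,
                                                    feature_width = 5),
                 protein = protein_encoder_config(hidden = 2, input_width = 3),
                 seed = 6)
  v <- matrix(rnorm(5), 1, 5)
  g <- toy_graph(v, matrix(integer(0), 0, 2))
  lr <- function(x) ifelse(x > 0, x, 0.01 * x)
  h <- v
  for (l in 1:2) h <- lr(h %*% m$params$comp$layers[[l]]$W +
                           m$params$comp$layers[[l]]$b)
  expected <- drop(h %*% m$params$comp$proj$W + m$params$comp$proj$b)
  expect_equal(encode_compound(g, m), expected, tolerance = 1e-12)
})

test_that("GraphSAGE two-node path matches a manual forward pass", {
  # width-2 features, one layer, hand-set weights: update is
  # leakyrelu(W . concat(h_v, mean of neighbours))
  m <- cpi_model("regression",
                 compound = compound_encoder_config("graphsage", n_layers = 1,
                                                    hidden = 2, out_dim = 2,
                                                    feature_width = 2),
                 protein = protein_encoder_config(hidden = 2, input_width = 3),
                 seed = 1)
  W <- matrix(c(1, 0, 0, 0,
                0, 1, 1, 0), 4, 2)  # out1 = self1, out2 = self2 + neigh1
  m$params$comp$layers[[1]] <- list(W = W, b = c(0, 0))
  m$params$comp$proj <- list(W = diag(2), b = c(0, 0))
  f <- matrix(c(1, 2,
                3, 5), 2, 2, byrow = TRUE)
  g <- toy_graph(f, matrix(c(1L, 2L), 1, 2))
  # node1: concat((1,2),(3,5)) -> (1, 2+3) = (1,5); node2: (3, 5+1) = (3,6)
  # mean pooling -> (2, 5.5); identity projection
  expect_equal(encode_compound(g, m), c(2, 5.5), tolerance = 1e-12)
})

test_that("tiny LSTM reproduces a hand-stepped recurrence", {
  m <- cpi_model("regression",
                 compound = compound_encoder_config(hidden = 2, out_dim = 2,
                                                    feature_width = 2),
                 protein = protein_encoder_config("lstm", hidden = 2,
                                                  input_width = 2),
                 seed = 8)
  set.seed(9)
  prot <- list(Wx = matrix(rnorm(2 * 8), 2, 8),
               Wh = matrix(rnorm(2 * 8), 2, 8), b = rnorm(8))
  m$params$prot <- prot
  X <- matrix(rnorm(4), 2, 2)
  # independent plain-R oracle of the standard LSTM equations
  sg <- function(x) 1 / (1 + exp(-x))
  h <- c(0, 0); cc <- c(0, 0); hs <- NULL
  for (t in 1:2) {
    z <- drop(X[t, ] %*% prot$Wx + h %*% prot$Wh + prot$b)
    i <- sg(z[1:2]); f <- sg(z[3:4]); g <- tanh(z[5:6]); o <- sg(z[7:8])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    hs <- rbind(hs, h)
  }
  expect_equal(encode_protein(toy_embedding(X), m), colMeans(hs),
               tolerance = 1e-12)
})

test_that("L = 1 protein encoding equals its single hidden state", {
  for (cell in c("lstm", "gru", "rnn")) {
    m <- cpi_model("regression",
                   compound = compound_encoder_config(hidden = 4, out_dim = 2),
                   protein = protein_encoder_config(cell, hidden = 3,
                                                    input_width = 4),
                   seed = 3)
    x <- matrix(rnorm(4), 1, 4)
    one <- encode_protein(toy_embedding(x), m)
    two <- encode_protein(toy_embedding(rbind(x, x * 0)), m)
    expect_length(one, 3L)
    # the mean over one step is that step; a second step changes the mean
    expect_false(isTRUE(all.equal(one, two)))
  }
})

test_that("batched protein encoding equals unbatched (padding neutrality)", {
  for (cell in c("lstm", "gru", "rnn")) {
    m <- cpi_model("regression",
                   compound = compound_encoder_config(hidden = 4, out_dim = 2),
                   protein = protein_encoder_config(cell, hidden = 4,
                                                    input_width = 6),
                   seed = 5)
    set.seed(21)
    e1 <- toy_embedding(matrix(rnorm(5 * 6), 5, 6))
    e2 <- toy_embedding(matrix(rnorm(9 * 6), 9, 6))
    batched <- encode_protein(list(e1, e2), m)
    expect_equal(batched[1, ], encode_protein(e1, m), tolerance = 1e-10)
    expect_equal(batched[2, ], encode_protein(e2, m), tolerance = 1e-10)
  }
})

test_that("compound encodings are invariant to node permutations", {
  m <- study_model(dropout = 0)
  graphs <- lapply(c("CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1CC", "C1CCC(O)CC1"),
                   smiles_to_graph)
  set.seed(12)
  for (g in graphs) {
    h0 <- encode_compound(g, m)
    for (r in 1:10) {
      gp <- permute_graph(g, sample(g$atom_count))
      expect_equal(encode_compound(gp, m), h0, tolerance = 1e-8)
    }
  }
})

test_that("analytic gradients match numerical differentiation everywhere", {
  combos <- list(c("lstm", "graphsage", "kronecker_pair"),
                 c("gru", "gcn", "kronecker_triple"),
                 c("rnn", "graphsage", "concat"))
  graphs <- lapply(c("CCO", "c1ccccc1", "C"), smiles_to_graph)
  embs <- lapply(c("ACDEF", "MKT", "WYVQQQH"), embed_sequence,
                 spec = embedding_backend("onehot"))
  cb <- ns$pack_compound_batch(graphs)
  pb <- ns$pack_protein_batch(embs)
  y <- c(1.2, -0.5, 2.0)
  set.seed(33)
  for (cmb in combos) {
    m <- cpi_model("regression",
                   compound = compound_encoder_config(cmb[2], n_layers = 2,
                                                      hidden = 5, out_dim = 3),
                   protein = protein_encoder_config(cmb[1], hidden = 3,
                                                    input_width = 21),
                   fusion = cmb[3], head_hidden = 4, dropout = 0, seed = 7)
    fwd <- ns$model_forward(m, cb, pb, train = FALSE)
    bl <- ns$batch_loss(m, fwd, y)
    gr <- ns$model_backward(m, fwd$cache, bl$dZ2)
    gflat <- unlist(gr[c("prot", "comp", "head")], use.names = FALSE)
    flat <- unlist(m$params, use.names = FALSE)
    loss_at <- function(f) {
      m2 <- m
      m2$params <- ns$unflatten(f, m$params)
      ns$batch_loss(m2, ns$model_forward(m2, cb, pb, FALSE), y)$loss
    }
    idx <- sample(length(flat), 20L)
    for (i in idx) {
      e <- 1e-6
      up <- flat; up[i] <- up[i] + e
      dn <- flat; dn[i] <- dn[i] - e
      num <- (loss_at(up) - loss_at(dn)) / (2 * e)
      relerr <- abs(gflat[i] - num) / max(1e-4, abs(num) + abs(gflat[i]))
      expect_lt(relerr, 5e-3)
    }
    # gradient flow: every parameter tensor receives some gradient
    for (grp in c("prot", "comp", "head")) {
      leaves <- unlist(gr[[grp]], use.names = FALSE)
      expect_true(any(leaves != 0), label = paste("grad flow", grp))
    }
  }
})

test_that("parameter count is a deterministic function of the configs", {
  m <- cpi_model("regression",
                 compound = compound_encoder_config("graphsage", n_layers = 2,
                                                    hidden = 8, out_dim = 4,
                                                    feature_width = 10),
                 protein = protein_encoder_config("lstm", hidden = 3,
                                                  input_width = 7),
                 fusion = "kronecker_pair", head_hidden = 5, seed = 1)
  # independent count: LSTM (7*12 + 3*12 + 12), SAGE layers
  # (20*8+8, 16*8+8), projection (8*4+4), head ((4+1)*(3+1)=20 -> 5 -> 1)
  expected <- (7 * 12 + 3 * 12 + 12) + (20 * 8 + 8) + (16 * 8 + 8) +
    (8 * 4 + 4) + (20 * 5 + 5) + (5 * 1 + 1)
  expect_equal(n_params(m), expected)
  m2 <- cpi_model("regression",
                  compound = m$config$compound, protein = m$config$protein,
                  fusion = "kronecker_pair", head_hidden = 5, seed = 99)
  expect_equal(n_params(m2), expected)
})

test_that("checkpoints round-trip and validate shapes on load", {
  m <- study_model(seed = 13)
  dir <- tempfile()
  save_model(m, dir)
  back <- load_model(dir)
  expect_equal(back$params, m$params)
  expect_equal(back$config$joint_width, m$config$joint_width)
  # corrupt the weights blob: loading must fail the shape check
  w <- readRDS(file.path(dir, "weights.rds"))
  w$head$W2 <- w$head$W2[, 1, drop = FALSE][1:2, , drop = FALSE]
  saveRDS(w, file.path(dir, "weights.rds"))
  expect_error(load_model(dir), "mismatch")
})

test_that("zero-atom and mismatched inputs are rejected", {
  m <- study_model()
  expect_error(encode_compound(list(), m), "molecular_graph")
  e <- embed_sequence("ACD", embedding_backend("onehot"))
  m2 <- cpi_model("regression",
                  protein = protein_encoder_config(hidden = 4,
                                                   input_width = 50),
                  compound = compound_encoder_config(hidden = 4, out_dim = 2),
                  seed = 1)
  expect_error(encode_protein(e, m2), "width")
})
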