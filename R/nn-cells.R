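# Batched variable-length recurrent cells (RNN / GRU / LSTM) with manual
# backpropagation through time. Sequences in a batch are zero-padded to the
# longest length; a 0/1 mask guarantees padded steps neither change the
# recurrent state nor contribute to the mean-pooled output, so batched and
# unbatched encodings agree (padding neutrality).
#
# The encoder output is the arithmetic mean over the per-step hidden states
# of each sequence's real steps.

sigmoid <- function(x) 1 / (1 + exp(-x))

rnn_gate_mult <- function(cell) switch(cell, lstm = 4L, gru = 3L, rnn = 1L)

# X: list over time of B x h input matrices; mask: B x T; lens: B
# params: list(Wx, Wh, b)
rnn_cell_forward <- function(cell, params, X, mask, lens) {
  Tn <- length(X)
  B <- nrow(X[[1L]])
  d <- nrow(params$Wh)
  h <- matrix(0, B, d)
  cst <- matrix(0, B, d)
  S <- matrix(0, B, d)
  steps <- vector("list", Tn)
  Bb <- matrix(params$b, B, length(params$b), byrow = TRUE)
  for (t in seq_len(Tn)) {
    m <- mask[, t]
    xt <- X[[t]]
    hprev <- h
    cprev <- cst
    if (cell == "lstm") {
      z <- xt %*% params$Wx + hprev %*% params$Wh + Bb
      i <- sigmoid(z[, 1:d, drop = FALSE])
      f <- sigmoid(z[, d + 1:d, drop = FALSE])
      g <- tanh(z[, 2L * d + 1:d, drop = FALSE])
      o <- sigmoid(z[, 3L * d + 1:d, drop = FALSE])
      cnew <- f * cprev + i * g
      tc <- tanh(cnew)
      hnew <- o * tc
      steps[[t]] <- list(i = i, f = f, g = g, o = o, cprev = cprev,
                         cnew = cnew, tc = tc, hprev = hprev, m = m)
      cst <- m * cnew + (1 - m) * cprev
    } else if (cell == "gru") {
      zx <- xt %*% params$Wx + Bb
      zh <- hprev %*% params$Wh
      r <- sigmoid(zx[, 1:d, drop = FALSE] + zh[, 1:d, drop = FALSE])
      u <- sigmoid(zx[, d + 1:d, drop = FALSE] + zh[, d + 1:d, drop = FALSE])
      hn_h <- zh[, 2L * d + 1:d, drop = FALSE]
      n <- tanh(zx[, 2L * d + 1:d, drop = FALSE] + r * hn_h)
      hnew <- (1 - u) * n + u * hprev
      steps[[t]] <- list(r = r, u = u, n = n, hn_h = hn_h, hprev = hprev,
                         m = m)
    } else {
      a <- xt %*% params$Wx + hprev %*% params$Wh + Bb
      hnew <- tanh(a)
      steps[[t]] <- list(hnew = hnew, hprev = hprev, m = m)
    }
    h <- m * hnew + (1 - m) * hprev
    S <- S + m * hnew
  }
  Hp <- S / lens
  list(Hp = Hp, cache = list(cell = cell, steps = steps, X = X, lens = lens,
                             d = d, B = B))
}

# dHp: B x d gradient of the loss wrt the mean-pooled hidden state.
# Returns gradients for Wx, Wh, b. Input gradients are not propagated
# (embeddings are fixed features).
rnn_cell_backward <- function(params, cache, dHp) {
  cell <- cache$cell
  d <- cache$d
  B <- cache$B
  dS <- dHp / cache$lens
  dWx <- array(0, dim(params$Wx))
  dWh <- array(0, dim(params$Wh))
  db <- numeric(length(params$b))
  dh <- matrix(0, B, d)
  dc <- matrix(0, B, d)
  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    m <- st$m
    xt <- cache$X[[t]]
    dhnew <- m * (dh + dS)
    dh_prev <- (1 - m) * dh
    if (cell == "lstm") {
      dcnew <- m * dc
      dc_prev <- (1 - m) * dc
      do <- dhnew * st$tc
      dtc <- dhnew * st$o
      dcnew <- dcnew + dtc * (1 - st$tc^2)
      df <- dcnew * st$cprev
      dc_prev <- dc_prev + dcnew * st$f
      di <- dcnew * st$g
      dg <- dcnew * st$i
      dz <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do * st$o * (1 - st$o))
      dWx <- dWx + crossprod(xt, dz)
      dWh <- dWh + crossprod(st$hprev, dz)
      db <- db + colSums(dz)
      dh <- dh_prev + dz %*% t(params$Wh)
      dc <- dc_prev
    } else if (cell == "gru") {
      dn <- dhnew * (1 - st$u)
      du <- dhnew * (st$hprev - st$n)
      dh_prev <- dh_prev + dhnew * st$u
      da_n <- dn * (1 - st$n^2)
      dr <- da_n * st$hn_h
      da_r <- dr * st$r * (1 - st$r)
      da_u <- du * st$u * (1 - st$u)
      dz <- cbind(da_r, da_u, da_n)
      dWx <- dWx + crossprod(xt, dz)
      db <- db + colSums(dz)
      # hidden-side paths: r and u gates use Wh directly; n uses r * (h Whn)
      dzh <- cbind(da_r, da_u, da_n * st$r)
      dWh <- dWh + crossprod(st$hprev, dzh)
      dh <- dh_prev + dzh %*% t(params$Wh)
    } else {
      da <- dhnew * (1 - st$hnew^2)
      dWx <- dWx + crossprod(xt, da)
      dWh <- dWh + crossprod(st$hprev, da)
      db <- db + colSums(da)
      dh <- dh_prev + da %*% t(params$Wh)
    }
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# Pack residue embeddings into padded time-major batch pieces.
pack_protein_batch <- function(embeddings) {
  mats <- lapply(embeddings, function(e) e$matrix)
  lens <- vapply(mats, nrow, integer(1))
  h <- ncol(mats[[1L]])
  B <- length(mats)
  Tn <- max(lens)
  X <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(0, B, h)
    live <- which(lens >= t)
    for (b in live) xt[b, ] <- mats[[b]][t, ]
    X[[t]] <- xt
  }
  mask <- outer(lens, seq_len(Tn), ">=") * 1
  list(X = X, mask = mask, lens = lens, h = h, B = B)
}
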