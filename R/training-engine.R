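#' Training configuration
#'
#' Defaults follow the grid-searched optimum of the method: minibatch Adam
#' with batch size 32 and learning rate 1e-4, at most 100 epochs, early
#' stopping when the validation loss fails to improve (strict decrease)
#' for 10 consecutive epochs. The loss is MSE for regression and
#' cross-entropy for classification, chosen by the model's task.
#'
#' @param batch_size Minibatch size (>= 1).
#' @param lr Adam learning rate.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs (<= max_epochs).
#' @param seed Integer seed controlling shuffling and dropout; a fixed
#'   (seed, data, config) triple reproduces the loss history exactly.
#' @param ring_size Number of most recent per-epoch checkpoints retained
#'   for the parameter ensemble (default 10).
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @param freeze_protein Do not update the protein-branch weights.
#' @param verbose Print one line per epoch.
#' @return A `"train_config"`.
#' @export
train_config <- function(batch_size = 32L, lr = 1e-4, max_epochs = 100L,
                         patience = 10L, seed = 1L, ring_size = 10L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         freeze_protein = FALSE, verbose = FALSE) {
  stopifnot(batch_size >= 1L, lr > 0, max_epochs >= 0L,
            patience <= max(max_epochs, 1L), ring_size >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 ring_size = as.integer(ring_size), beta1 = beta1,
                 beta2 = beta2, eps = eps,
                 freeze_protein = isTRUE(freeze_protein),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# length-bucketed batches: indices ordered by protein length, then chunked
make_batches <- function(data, idx, batch_size) {
  lens <- vapply(data$embeddings[data$pairs$protein_key[idx]],
                 function(e) e$L, integer(1))
  idx <- idx[order(lens)]
  split(idx, ceiling(seq_along(idx) / batch_size))
}

batch_inputs <- function(data, idx) {
  list(cb = pack_compound_batch(data$graphs[data$pairs$compound_key[idx]]),
       pb = pack_protein_batch(data$embeddings[data$pairs$protein_key[idx]]),
       y = data$pairs$label[idx])
}

eval_loss <- function(model, binputs) {
  tot <- 0
  n <- 0L
  for (bi in binputs) {
    fwd <- model_forward(model, bi$cb, bi$pb, train = FALSE)
    tot <- tot + batch_loss(model, fwd, bi$y)$loss * length(bi$y)
    n <- n + length(bi$y)
  }
  tot / n
}

# cheap structural unflatten (same contract as utils::relist for our
# nested list-of-arrays parameter containers)
unflatten <- function(flat, skel) {
  i <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    v <- flat[(i + 1L):(i + n)]
    i <<- i + n
    if (!is.null(dim(x))) dim(v) <- dim(x)
    v
  }
  walk(skel)
}

adam_state <- function(flat) list(m = numeric(length(flat)),
                                  v = numeric(length(flat)), t = 0L)

adam_step <- function(state, flat, grad, cfg) {
  state$t <- state$t + 1L
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mhat <- state$m / (1 - cfg$beta1^state$t)
  vhat <- state$v / (1 - cfg$beta2^state$t)
  list(state = state, flat = flat - cfg$lr * mhat / (sqrt(vhat) + cfg$eps))
}

#' Train a CPI model
#'
#' Minimizes the task loss (MSE or cross-entropy) by minibatch Adam over
#' `train_data`, monitoring the loss on `val_data` after every epoch.
#' Training stops when the validation loss has not strictly decreased for
#' `patience` consecutive epochs, or at `max_epochs`. The returned model
#' carries the parameters that achieved the best validation loss; a ring
#' of the last (up to) `ring_size` per-epoch checkpoints is kept for
#' [parameter_ensemble_predict()].
#'
#' @param model A [cpi_model()] providing the initial parameters (for
#'   fine-tuning, a pretrained model).
#' @param train_data,val_data [cpi_dataset()] objects with non-empty pair
#'   tables; labels must match the model task (real pIC50 for regression,
#'   0/1 for classification).
#' @param config A [train_config()].
#' @return A `"cpi_train_result"`: `model` (best parameters), `history`
#'   (data frame epoch/train_loss/val_loss), `best_epoch`,
#'   `stopped_epoch`, `ring` (recent checkpoints, oldest first) and
#'   `config`.
#' @export
train_cpi <- function(model, train_data, val_data, config = train_config()) {
  stopifnot(inherits(model, "cpi_model"), inherits(config, "train_config"))
  check_dataset(train_data, model$config$task)
  check_dataset(val_data, model$config$task)
  n_train <- nrow(train_data$pairs)
  if (!n_train || !nrow(val_data$pairs))
    stop("empty training or validation split", call. = FALSE)

  params <- model$params
  flat <- unlist(params, use.names = FALSE)
  opt <- adam_state(flat)
  frozen <- if (config$freeze_protein) {
    tmpl <- params
    tmpl$prot <- lapply(tmpl$prot, function(x) array(1, dim(x) %||% length(x)))
    tmpl$comp <- rapply(tmpl$comp, function(x) x * 0, how = "replace")
    tmpl$head <- rapply(tmpl$head, function(x) x * 0, how = "replace")
    unlist(tmpl, use.names = FALSE) > 0
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  ring <- list()
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  stopped <- 0L

  with_seed(config$seed, {
    batches <- make_batches(train_data, seq_len(n_train), config$batch_size)
    binputs <- lapply(batches, function(b) batch_inputs(train_data, b))
    vinputs <- lapply(make_batches(val_data, seq_len(nrow(val_data$pairs)),
                                   config$batch_size),
                      function(b) batch_inputs(val_data, b))
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(batches))
      ep_loss <- 0
      for (bi_i in seq_along(ord)) {
        bi <- binputs[[ord[bi_i]]]
        model$params <- params
        fwd <- model_forward(model, bi$cb, bi$pb, train = TRUE)
        bl <- batch_loss(model, fwd, bi$y)
        if (!is.finite(bl$loss))
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi_i),
               call. = FALSE)
        ep_loss <- ep_loss + bl$loss * length(bi$y)
        grads <- model_backward(model, fwd$cache, bl$dZ2)
        gflat <- unlist(grads[c("prot", "comp", "head")], use.names = FALSE)
        if (!is.null(frozen)) gflat[frozen] <- 0
        st <- adam_step(opt, flat, gflat, config)
        opt <- st$state
        flat <- st$flat
        params <- unflatten(flat, params)
      }
      model$params <- params
      val_loss <- eval_loss(model, vinputs)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / n_train,
                                  val_loss = val_loss))
      ring[[length(ring) + 1L]] <- params
      if (length(ring) > config$ring_size) ring <- ring[-1L]
      if (config$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        ep_loss / n_train, val_loss))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      stopped <- epoch
      if (wait >= config$patience) break
    }
  })

  model$params <- if (best_epoch > 0L) best_params else params
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 stopped_epoch = stopped, ring = ring, config = config),
            class = "cpi_train_result")
}

#' Continue training from pretrained weights
#'
#' Fine-tuning keeps the architecture fixed and continues optimization of
#' all layers (optionally freezing the protein branch via the config) on a
#' target-specific dataset; the loop contract is identical to
#' [train_cpi()]. With `max_epochs = 0` the pretrained parameters are
#' returned unchanged.
#'
#' @inheritParams train_cpi
#' @param pretrained A trained [cpi_model()] (e.g. `result$model`).
#' @return A `"cpi_train_result"`.
#' @export
finetune_cpi <- function(pretrained, train_data, val_data,
                         config = train_config()) {
  stopifnot(inherits(pretrained, "cpi_model"))
  ref <- cpi_model(task = pretrained$config$task,
                   compound = pretrained$config$compound,
                   protein = pretrained$config$protein,
                   fusion = pretrained$config$fusion,
                   head_hidden = pretrained$config$head_hidden,
                   dropout = pretrained$config$dropout,
                   leaky_slope = pretrained$config$leaky_slope,
                   seed = pretrained$config$seed)
  check_same_shapes(ref$params, pretrained$params)
  if (config$max_epochs == 0L) {
    return(structure(list(model = pretrained,
                          history = data.frame(epoch = integer(0),
                                               train_loss = numeric(0),
                                               val_loss = numeric(0)),
                          best_epoch = 0L, stopped_epoch = 0L,
                          ring = list(pretrained$params), config = config),
                     class = "cpi_train_result"))
  }
  train_cpi(pretrained, train_data, val_data, config)
}

#' Predict with a trained model
#'
#' @param object A [cpi_model()].
#' @param data A [cpi_dataset()].
#' @param idx Optional row indices of `data$pairs` (default all).
#' @param type `"response"`: pIC50 for regression, positive-class
#'   probability for classification. `"prob"`: the full two-column
#'   probability matrix (classification only).
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Numeric vector (or matrix for `type = "prob"`), in `idx` order.
#' @export
predict.cpi_model <- function(object, data, idx = NULL,
                              type = c("response", "prob"),
                              batch_size = 64L, ...) {
  type <- match.arg(type)
  if (is.null(idx)) idx <- seq_len(nrow(data$pairs))
  if (!length(idx)) return(numeric(0))
  out <- NULL
  pos <- integer(0)
  for (b in make_batches(data, idx, batch_size)) {
    bi <- batch_inputs(data, b)
    fwd <- model_forward(object, bi$cb, bi$pb, train = FALSE)
    pred <- if (object$config$task == "regression") cbind(fwd$pred)
            else fwd$pred
    out <- rbind(out, pred)
    pos <- c(pos, b)
  }
  out <- out[match(idx, pos), , drop = FALSE]
  if (object$config$task == "regression") return(drop(out[, 1L]))
  if (type == "prob") return(out)
  drop(out[, 2L])
}

#' Parameter-ensemble prediction
#'
#' Averages the predictions of the checkpoints retained from the last
#' (up to ten) training epochs of a single run.
#'
#' @param result A [train_cpi()] result with a non-empty checkpoint ring.
#' @param data A [cpi_dataset()].
#' @param idx Optional row indices (default all).
#' @return Numeric vector: the arithmetic mean of the per-checkpoint
#'   predictions.
#' @export
parameter_ensemble_predict <- function(result, data, idx = NULL) {
  stopifnot(inherits(result, "cpi_train_result"))
  if (!length(result$ring)) stop("empty checkpoint ring", call. = FALSE)
  model <- result$model
  acc <- NULL
  for (p in result$ring) {
    model$params <- p
    pred <- predict(model, data, idx)
    acc <- if (is.null(acc)) pred else acc + pred
  }
  acc / length(result$ring)
}

#' Network-ensemble prediction
#'
#' Averages the predictions of several independently trained networks
#' (e.g. with different hyperparameters) on the same task.
#'
#' @param results List of [train_cpi()] results (>= 1), all with the same
#'   task.
#' @param data A [cpi_dataset()].
#' @param idx Optional row indices (default all).
#' @return Numeric vector: the member-mean prediction.
#' @export
nn_ensemble_predict <- function(results, data, idx = NULL) {
  stopifnot(length(results) >= 1L)
  tasks <- vapply(results, function(r) r$model$config$task, character(1))
  if (length(unique(tasks)) != 1L)
    stop("ensemble members trained on different tasks: ",
         paste(unique(tasks), collapse = ", "), call. = FALSE)
  preds <- lapply(results, function(r) predict(r$model, data, idx))
  Reduce(`+`, preds) / length(preds)
}

#' @export
print.cpi_train_result <- function(x, ...) {
  cat(sprintf(paste0("<cpi_train_result> epochs=%d best_epoch=%d ",
                     "best_val=%.5f ring=%d\n"),
              x$stopped_epoch, x$best_epoch,
              if (nrow(x$history)) min(x$history$val_loss) else NA_real_,
              length(x$ring)))
  invisible(x)
}
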