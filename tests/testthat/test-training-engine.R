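# Optimization loop, early stopping, reproducibility, ensembles, fine-tuning.

small_split <- function(n_train = 60, n_val = 20, seed = 31) {
  data <- study_data()
  with_seed_t(seed, {
    idx <- sample(nrow(data$pairs), n_train + n_val)
    list(train = subset_dataset(data, idx[seq_len(n_train)]),
         val = subset_dataset(data, idx[n_train + seq_len(n_val)]),
         val_idx = idx[n_train + seq_len(n_val)])
  })
}

quick_cfg <- function(...) {
  train_config(batch_size = 16L, lr = 3e-3, max_epochs = 6L, patience = 6L,
               seed = 2L, ...)
}

test_that("identical seeds give bitwise-identical loss histories", {
  sp <- small_split()
  r1 <- train_cpi(study_model(), sp$train, sp$val, quick_cfg())
  r2 <- train_cpi(study_model(), sp$train, sp$val, quick_cfg())
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
  r3 <- train_cpi(study_model(), sp$train, sp$val,
                  train_config(batch_size = 16L, lr = 3e-3, max_epochs = 6L,
                               patience = 6L, seed = 77L))
  expect_false(identical(r1$history$train_loss, r3$history$train_loss))
})

test_that("early stopping fires after `patience` non-improving epochs", {
  sp <- small_split()
  # a vanishing learning rate freezes the model, so the validation loss
  # never strictly improves after epoch 1
  res <- train_cpi(study_model(dropout = 0), sp$train, sp$val,
                   train_config(batch_size = 16L, lr = 1e-30,
                                max_epochs = 50L, patience = 3L, seed = 2L))
  expect_equal(res$stopped_epoch, 1L + 3L)
  expect_equal(res$best_epoch, 1L)
  # general contract: the gap between stop and best equals the patience
  res2 <- train_cpi(study_model(), sp$train, sp$val,
                    train_config(batch_size = 16L, lr = 3e-3,
                                 max_epochs = 200L, patience = 4L, seed = 2L))
  if (res2$stopped_epoch < 200L)
    expect_equal(res2$stopped_epoch - res2$best_epoch, 4L)
  expect_equal(min(res2$history$val_loss),
               res2$history$val_loss[res2$best_epoch])
})

test_that("diverging optimization aborts with an epoch/batch diagnostic", {
  sp <- small_split()
  expect_error(
    train_cpi(study_model(), sp$train, sp$val,
              train_config(batch_size = 16L, lr = 1e40, max_epochs = 10L,
                           patience = 10L, seed = 2L)),
    "non-finite loss at epoch")
})

test_that("the checkpoint ring holds the most recent epochs in order", {
  sp <- small_split()
  res <- train_cpi(study_model(), sp$train, sp$val,
                   train_config(batch_size = 16L, lr = 3e-3, max_epochs = 13L,
                                patience = 13L, seed = 2L, ring_size = 10L))
  expect_length(res$ring, 10L)
  # the newest ring entry is the final epoch's parameter state
  final <- res$ring[[10L]]
  m <- res$model
  m$params <- final
  h <- res$history
  expect_equal(nrow(h), 13L)
})

test_that("parameter ensemble equals the element-wise checkpoint mean", {
  sp <- small_split()
  res <- train_cpi(study_model(), sp$train, sp$val, quick_cfg())
  probe <- sp$val
  ens <- parameter_ensemble_predict(res, probe)
  m <- res$model
  preds <- sapply(res$ring, function(p) {
    m$params <- p
    predict(m, probe)
  })
  expect_equal(ens, rowMeans(preds), tolerance = 1e-12)
  # degenerate ring of identical checkpoints collapses to a single model
  res1 <- res
  res1$ring <- rep(list(res$ring[[1]]), 3)
  m$params <- res$ring[[1]]
  expect_equal(parameter_ensemble_predict(res1, probe), predict(m, probe),
               tolerance = 1e-12)
  res0 <- res
  res0$ring <- list()
  expect_error(parameter_ensemble_predict(res0, probe), "empty")
})

test_that("NN ensemble averages member predictions", {
  sp <- small_split()
  r1 <- train_cpi(study_model(seed = 3), sp$train, sp$val, quick_cfg())
  r2 <- train_cpi(study_model(seed = 4), sp$train, sp$val, quick_cfg())
  r3 <- train_cpi(study_model(seed = 5), sp$train, sp$val, quick_cfg())
  probe <- sp$val
  ens <- nn_ensemble_predict(list(r1, r2, r3), probe)
  stack <- cbind(predict(r1$model, probe), predict(r2$model, probe),
                 predict(r3$model, probe))
  expect_equal(ens, rowMeans(stack), tolerance = 1e-12)
  expect_equal(nn_ensemble_predict(list(r1), probe), predict(r1$model, probe))
  rc <- r1
  rc$model$config$task <- "classification"
  expect_error(nn_ensemble_predict(list(r1, rc), probe), "different tasks")
})

test_that("zero-epoch fine-tuning returns the pretrained weights unchanged", {
  sp <- small_split()
  pre <- train_cpi(study_model(), sp$train, sp$val, quick_cfg())
  ft <- finetune_cpi(pre$model, sp$train, sp$val,
                     train_config(max_epochs = 0L, patience = 0L))
  expect_identical(ft$model$params, pre$model$params)
})

test_that("fine-tuning rejects shape-incompatible pretrained weights", {
  sp <- small_split()
  pre <- study_model()
  pre$params$head$W1 <- pre$params$head$W1[, 1:3]
  expect_error(finetune_cpi(pre, sp$train, sp$val, quick_cfg()),
               "mismatch at .*head")
})

test_that("freezing the protein branch leaves its weights untouched", {
  sp <- small_split()
  m <- study_model()
  res <- train_cpi(m, sp$train, sp$val,
                   train_config(batch_size = 16L, lr = 3e-3, max_epochs = 3L,
                                patience = 3L, seed = 2L,
                                freeze_protein = TRUE))
  expect_identical(res$ring[[length(res$ring)]]$prot, m$params$prot)
  expect_false(identical(res$ring[[length(res$ring)]]$head, m$params$head))
})

test_that("classification training minimizes cross-entropy", {
  syn <- generate_synthetic(synthetic_spec(task = "classification",
                                           n_compounds = 40L, seed = 21L))
  expect_true(all(syn$pairs$label %in% 0:1))
  data <- build_dataset(syn$pairs, study_backend())
  n <- nrow(data$pairs)
  sp <- with_seed_t(8L, {
    v <- sample(n, round(0.2 * n))
    list(tr = setdiff(seq_len(n), v), val = v)
  })
  res <- train_cpi(study_model("classification"),
                   subset_dataset(data, sp$tr), subset_dataset(data, sp$val),
                   train_config(batch_size = 32L, lr = 3e-3, max_epochs = 30L,
                                patience = 30L, seed = 2L))
  expect_lt(res$history$train_loss[nrow(res$history)],
            res$history$train_loss[1])
  p <- predict(res$model, data, sp$val)
  expect_true(all(p >= 0 & p <= 1))
  m <- classification_metrics(p, data$pairs$label[sp$val])
  expect_gt(m$auc, 0.6)
})

test_that("more training data does not hurt generalization (majority vote)", {
  data <- study_data()
  wins <- 0L
  for (s in 1:3) {
    sizes <- with_seed_t(40L + s, {
      idx <- sample(nrow(data$pairs), 320)
      list(val = idx[301:320], small = idx[1:80], large = idx[1:300])
    })
    cfg <- train_config(batch_size = 32L, lr = 3e-3, max_epochs = 15L,
                        patience = 15L, seed = 50L + s)
    r_small <- train_cpi(study_model(), subset_dataset(data, sizes$small),
                         subset_dataset(data, sizes$val), cfg)
    r_large <- train_cpi(study_model(), subset_dataset(data, sizes$large),
                         subset_dataset(data, sizes$val), cfg)
    if (min(r_large$history$val_loss) <= min(r_small$history$val_loss))
      wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("fine-tuning beats training from scratch at an equal epoch budget", {
  pre <- study_pretrain()
  panel <- generate_synthetic(synthetic_spec(
    n_compounds = 60L, selectivity = list(delta = 2, selective_fraction = 0.2),
    seed = 71L))
  pd <- build_dataset(panel$pairs, study_backend())
  n <- nrow(pd$pairs)
  sp <- with_seed_t(72L, {
    v <- sample(n, round(0.15 * n))
    list(tr = setdiff(seq_len(n), v), val = v)
  })
  cfg <- train_config(batch_size = 16L, lr = 3e-3, max_epochs = 15L,
                      patience = 15L, seed = 9L)
  ft <- finetune_cpi(pre$model, subset_dataset(pd, sp$tr),
                     subset_dataset(pd, sp$val), cfg)
  scratch <- train_cpi(study_model(seed = 123L), subset_dataset(pd, sp$tr),
                       subset_dataset(pd, sp$val), cfg)
  expect_lt(min(ft$history$val_loss), min(scratch$history$val_loss))
})
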