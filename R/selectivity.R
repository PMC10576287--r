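#' Per-compound selectivity report against two targets
#'
#' Predicts every compound against two protein targets with one model and
#' derives per-compound selectivity: `delta = prediction(A) -
#' prediction(B)` (pIC50 difference for regression, difference of
#' positive-class probabilities for classification), plus, for
#' classification, a discordance flag (active against exactly one
#' target). Regression compounds with `|delta| >= sel_threshold` (default
#' 1.0, one order of magnitude in IC50) are flagged selective.
#'
#' @param model A trained [cpi_model()].
#' @param compounds Character vector of SMILES, or a named list of
#'   `molecular_graph` objects.
#' @param target_a,target_b Amino-acid sequences of the two targets.
#' @param backend The [embedding_backend()] matching the model's protein
#'   input width.
#' @param sel_threshold Regression selectivity call threshold (pIC50
#'   units).
#' @param labels_a,labels_b Optional true labels per compound, echoed
#'   into the report for agreement checks.
#' @return A data frame of class `"selectivity_report"`, sorted by
#'   decreasing `|delta|`: compound, pred_a, pred_b, delta, and
#'   (classification) active_a/active_b/discordant or (regression)
#'   selective.
#' @export
selectivity_report <- function(model, compounds, target_a, target_b,
                               backend = embedding_backend("onehot"),
                               sel_threshold = 1.0,
                               labels_a = NULL, labels_b = NULL) {
  stopifnot(inherits(model, "cpi_model"))
  if (is.character(compounds)) {
    ft <- graphs_from_table(compounds)
    if (length(ft$failures))
      stop("unfeaturizable compounds: ",
           paste(utils::head(ft$failures, 3L), collapse = ", "),
           call. = FALSE)
    keys <- unname(ft$key_map[compounds])
    graphs <- ft$graphs[keys]
    ids <- compounds
  } else {
    graphs <- compounds
    ids <- names(compounds) %||% as.character(seq_along(compounds))
  }
  emb <- lapply(list(A = target_a, B = target_b), function(s)
    tryCatch(embed_sequence(s, backend),
             error = function(e) stop("unembeddable target sequence: ",
                                      conditionMessage(e), call. = FALSE)))
  n <- length(graphs)
  pairs <- data.frame(compound_key = rep(names(graphs), 2L),
                      protein_key = rep(c("A", "B"), each = n),
                      label = 0)
  data <- cpi_dataset(pairs, graphs, emb)
  pred <- predict(model, data)
  pa <- pred[seq_len(n)]
  pb <- pred[n + seq_len(n)]
  rep_df <- data.frame(compound = ids, pred_a = pa, pred_b = pb,
                       delta = pa - pb, stringsAsFactors = FALSE)
  if (model$config$task == "classification") {
    rep_df$active_a <- pa >= 0.5
    rep_df$active_b <- pb >= 0.5
    rep_df$discordant <- xor(rep_df$active_a, rep_df$active_b)
  } else {
    rep_df$selective <- abs(rep_df$delta) >= sel_threshold
  }
  if (!is.null(labels_a)) rep_df$label_a <- labels_a
  if (!is.null(labels_b)) rep_df$label_b <- labels_b
  rep_df <- rep_df[order(-abs(rep_df$delta)), , drop = FALSE]
  rownames(rep_df) <- NULL
  class(rep_df) <- c("selectivity_report", "data.frame")
  rep_df
}

#' Missing-entry fine-tuning sweep
#'
#' Emulates transferring a pretrained CPI model to a small selectivity
#' panel with incomplete activity data. For each missing fraction m and
#' each of k repeats, a uniformly random m-share of the panel's
#' (compound, target) entries is hidden; the pretrained model is
#' fine-tuned on the visible share (with a held-out validation slice for
#' early stopping) and evaluated on the hidden share. Hidden sets are
#' re-drawn per repeat from the given seed, so the whole sweep is
#' reproducible.
#'
#' @param panel A [cpi_dataset()] over the selectivity panel.
#' @param pretrained A trained [cpi_model()].
#' @param fractions Missing fractions, each in (0, 1).
#' @param k Number of repeats per fraction (cross-validation style).
#' @param seed Integer seed.
#' @param config [train_config()] for the fine-tuning runs.
#' @param val_fraction Share of the visible entries used for early
#'   stopping.
#' @return A tidy data frame: `fraction`, `fold`, `metric`, `value`
#'   (metrics: mse/pearson/rm2 for regression, auc/aupr for
#'   classification).
#' @export
missing_entry_sweep <- function(panel, pretrained, fractions = c(0.95, 0.9,
                                                                 0.8, 0.7),
                                k = 5L, seed = 1L, config = train_config(),
                                val_fraction = 0.1) {
  stopifnot(inherits(panel, "cpi_dataset"), inherits(pretrained, "cpi_model"))
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie in (0, 1)", call. = FALSE)
  n <- nrow(panel$pairs)
  task <- pretrained$config$task
  out <- NULL
  for (fi in seq_along(fractions)) {
    m <- fractions[fi]
    n_vis <- n - round(m * n)
    if (n_vis < k)
      stop(sprintf("visible share (%d entries) smaller than k = %d at missing fraction %.2f",
                   n_vis, k, m), call. = FALSE)
    for (fold in seq_len(k)) {
      draw <- with_seed(seed + 1000L * fi + fold, {
        hidden <- sample(n, round(m * n))
        visible <- setdiff(seq_len(n), hidden)
        val <- sample(visible, max(1L, round(val_fraction * length(visible))))
        list(hidden = hidden, train = setdiff(visible, val), val = val)
      })
      cfg <- config
      cfg$seed <- config$seed + fold
      res <- finetune_cpi(pretrained, subset_dataset(panel, draw$train),
                          subset_dataset(panel, draw$val), cfg)
      pred <- predict(res$model, panel, draw$hidden)
      y <- panel$pairs$label[draw$hidden]
      vals <- if (task == "regression") {
        mm <- regression_metrics(pred, y)
        c(mse = mm$mse, pearson = mm$pearson, rm2 = as.numeric(mm$rm2))
      } else {
        mm <- classification_metrics(pred, y)
        c(auc = mm$auc, aupr = mm$aupr)
      }
      out <- rbind(out, data.frame(fraction = m, fold = fold,
                                   metric = names(vals),
                                   value = unname(vals)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarize a sweep as mean and sd per (fraction, metric)
#'
#' @param sweep A [missing_entry_sweep()] result.
#' @return Data frame with `fraction`, `metric`, `mean`, `sd`, `k`.
#' @export
summarize_sweep <- function(sweep) {
  agg <- stats::aggregate(value ~ fraction + metric, sweep,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        k = length(v)))
  out <- data.frame(fraction = agg$fraction, metric = agg$metric,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    k = agg$value[, "k"])
  out[order(out$metric, out$fraction), ]
}
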