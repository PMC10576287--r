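#' Split a pair table into cross-validation folds
#'
#' Four schemes:
#' \describe{
#'   \item{random}{pairs shuffled into k folds of near-equal size.}
#'   \item{cold_protein}{distinct proteins are partitioned into k groups
#'     and every pair follows its protein, so test proteins never occur
#'     in training.}
#'   \item{cold_compound}{symmetric, on compounds.}
#'   \item{blind}{proteins and compounds are partitioned independently;
#'     fold f's test set holds the pairs whose protein group and compound
#'     group both equal f. Pairs with mixed group membership are never
#'     tested but remain eligible for training in folds untouched by
#'     either of their groups.}
#' }
#'
#' @param records Data frame with `compound_key` and `protein_key` columns
#'   (e.g. the `pairs` slot of a [cpi_dataset()]).
#' @param scheme Split scheme.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return A `"split_assignment"`: list with `scheme`, `k`, `seed`,
#'   per-record `fold` (NA for blind-split pairs that are never tested),
#'   `protein_group`/`compound_group` (blind), and `n_dropped`.
#' @export
split_pairs <- function(records,
                        scheme = c("random", "cold_protein", "cold_compound",
                                   "blind"),
                        k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- nrow(records)
  part <- function(keys, what) {
    u <- unique(keys)
    if (length(u) < k)
      stop("too few distinct ", what, " for ", k, "-fold split (have ",
           length(u), ")", call. = FALSE)
    grp <- structure((sample.int(length(u)) %% k) + 1L, names = u)
    unname(grp[keys])
  }
  out <- with_seed(seed, switch(scheme,
    random = {
      if (n < k) stop("too few pairs for ", k, " folds (have ", n, ")",
                      call. = FALSE)
      list(fold = (sample.int(n) %% k) + 1L)
    },
    cold_protein = list(fold = part(records$protein_key, "proteins")),
    cold_compound = list(fold = part(records$compound_key, "compounds")),
    blind = {
      pg <- part(records$protein_key, "proteins")
      cg <- part(records$compound_key, "compounds")
      list(fold = ifelse(pg == cg, pg, NA_integer_),
           protein_group = pg, compound_group = cg)
    }))
  structure(c(out, list(scheme = scheme, k = as.integer(k),
                        seed = as.integer(seed),
                        n_dropped = sum(is.na(out$fold)), n = n)),
            class = "split_assignment")
}

#' Train/test indices of one fold
#'
#' @param assignment A [split_pairs()] result.
#' @param fold Fold number in 1..k.
#' @return List with integer `train` and `test` indices. For the blind
#'   scheme the training set excludes every pair sharing a protein or
#'   compound group with the fold's test set.
#' @export
fold_indices <- function(assignment, fold) {
  stopifnot(inherits(assignment, "split_assignment"),
            fold >= 1L, fold <= assignment$k)
  if (assignment$scheme == "blind") {
    test <- which(!is.na(assignment$fold) & assignment$fold == fold)
    train <- which(assignment$protein_group != fold &
                     assignment$compound_group != fold)
  } else {
    test <- which(assignment$fold == fold)
    train <- which(assignment$fold != fold)
  }
  list(train = train, test = test)
}

#' Serialize a split assignment to a delimited table
#'
#' @param assignment A [split_pairs()] result.
#' @param records The pair table it was computed on.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_split <- function(assignment, records, path) {
  df <- data.frame(compound_key = records$compound_key,
                   protein_key = records$protein_key,
                   scheme = assignment$scheme, seed = assignment$seed,
                   fold = assignment$fold)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regression metric suite
#'
#' MSE, Pearson correlation, and the external-validation metric
#' rm2 = r^2 * (1 - sqrt(r^2 - r0^2)), where r^2 is the squared Pearson
#' correlation (with intercept) and r0^2 comes from the least-squares fit
#' of labels on predictions through the origin
#' (r0^2 = 1 - sum((y - k*p)^2) / sum((y - mean(y))^2), k = sum(y*p)/sum(p^2)).
#' A negative argument of the square root (r^2 < r0^2) is clamped to 0 and
#' flagged via the `"clamped"` attribute on `rm2`.
#'
#' @param predictions,labels Equal-length numeric vectors, n >= 2;
#'   `labels` must not be constant (Pearson undefined).
#' @param origin `"labels_on_predictions"` (default, the convention of the
#'   rm2 literature) or the swapped variant.
#' @return List with `mse`, `pearson`, `rm2`.
#' @export
regression_metrics <- function(predictions, labels,
                               origin = c("labels_on_predictions",
                                          "predictions_on_labels")) {
  origin <- match.arg(origin)
  p <- as.numeric(predictions); y <- as.numeric(labels)
  if (length(p) != length(y))
    stop("length mismatch: ", length(p), " predictions vs ", length(y),
         " labels", call. = FALSE)
  n <- length(p)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(p) == 0)
    stop("Pearson undefined for a constant vector", call. = FALSE)
  mse <- mean((p - y)^2)
  pearson <- sum((p - mean(p)) * (y - mean(y))) /
    ((n - 1) * stats::sd(p) * stats::sd(y))
  r2 <- pearson^2
  if (origin == "predictions_on_labels") { a <- p; b <- y } else {
    a <- y; b <- p
  }
  kk <- sum(a * b) / sum(b^2)
  r02 <- 1 - sum((a - kk * b)^2) / sum((a - mean(a))^2)
  arg <- r2 - r02
  rm2 <- r2 * (1 - sqrt(max(arg, 0)))
  attr(rm2, "clamped") <- arg < 0
  list(mse = mse, pearson = pearson, rm2 = rm2)
}

#' Classification metric suite
#'
#' AUC is computed by the rank statistic (tied scores contribute 1/2),
#' AUPR by step integration of the precision-recall curve over blocks of
#' tied scores, and threshold metrics (accuracy, precision, recall, F1)
#' at a positive-class probability cutoff of 0.5. When only one class is
#' present, AUC and AUPR are returned as `NA` with a warning; threshold
#' metrics are still computed.
#'
#' @param scores Positive-class scores/probabilities.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold for the threshold metrics.
#' @return List with `auc`, `aupr`, `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  s <- as.numeric(scores); y <- as.integer(labels)
  if (length(s) != length(y))
    stop("length mismatch between scores and labels", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0L || nn == 0L) {
    warning("single-class labels: AUC/AUPR undefined")
    auc <- aupr <- NA_real_
  } else {
    r <- rank(s, ties.method = "average")
    auc <- (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
    # precision-recall step integration over tied-score blocks
    ord <- order(s, decreasing = TRUE)
    ys <- y[ord]; ss <- s[ord]
    block <- cumsum(!duplicated(ss))
    tp_b <- tapply(ys, block, sum)
    n_b <- tapply(ys, block, length)
    tp <- cumsum(tp_b)
    npred <- cumsum(n_b)
    prec <- tp / npred
    rec <- tp / np
    aupr <- sum(diff(c(0, rec)) * prec)
  }
  pred <- as.integer(s >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  accuracy <- mean(pred == y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(auc = auc, aupr = aupr, accuracy = accuracy, precision = precision,
       recall = recall, f1 = f1)
}

#' Cross-validated evaluation of a model family on a dataset
#'
#' For each fold: trains a fresh copy of `model` (same initial weights)
#' on the fold's training pairs and evaluates on its test pairs.
#'
#' @param model A [cpi_model()] (initial weights; re-used per fold).
#' @param data A [cpi_dataset()].
#' @param assignment A [split_pairs()] result over `data$pairs`.
#' @param config A [train_config()].
#' @param val_fraction Fraction of each fold's training pairs held out as
#'   the early-stopping validation split.
#' @return Data frame, one row per fold, with the task's metrics.
#' @export
evaluate_cv <- function(model, data, assignment, config = train_config(),
                        val_fraction = 0.1) {
  rows <- NULL
  for (f in seq_len(assignment$k)) {
    fi <- fold_indices(assignment, f)
    if (!length(fi$test) || length(fi$train) < 2L) next
    sp <- with_seed(config$seed + f, {
      v <- sample(fi$train, max(1L, round(val_fraction * length(fi$train))))
      list(val = v, tr = setdiff(fi$train, v))
    })
    res <- train_cpi(model, subset_dataset(data, sp$tr),
                     subset_dataset(data, sp$val), config)
    pred <- predict(res$model, data, fi$test)
    y <- data$pairs$label[fi$test]
    m <- if (model$config$task == "regression") {
      regression_metrics(pred, y)
    } else {
      classification_metrics(pred, y)
    }
    rows <- rbind(rows, data.frame(fold = f, n_test = length(fi$test),
                                   as.data.frame(lapply(m, as.numeric))))
  }
  rows
}
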