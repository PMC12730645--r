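confusion_counts <- function(truth, pred, C) {
  m <- matrix(0L, C, C)
  for (i in seq_along(truth))
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  m
}

#' Classification metrics from truth and prediction
#'
#' @param truth,pred label vectors (factors or coercible; aligned levels).
#' @param levels optional explicit class levels.
#' @return an object of class `capsnet_metrics`: accuracy (percent),
#'   per-class recall (percent), the confusion matrix (rows = truth) and
#'   its row-normalized form.
#' @export
classification_metrics <- function(truth, pred, levels = NULL) {
  lv <- levels %||% sort(unique(c(as.character(truth), as.character(pred))))
  tf <- factor(as.character(truth), levels = lv)
  pf <- factor(as.character(pred), levels = lv)
  conf <- table(truth = tf, predicted = pf)
  support <- rowSums(conf)
  norm <- conf / ifelse(support == 0, 1, support)
  structure(list(
    accuracy = 100 * sum(diag(conf)) / sum(conf),
    per_class_recall = 100 * ifelse(support == 0, NA, diag(conf) / support),
    confusion = unclass(conf), normalized = unclass(norm),
    n = sum(conf), levels = lv
  ), class = "capsnet_metrics")
}

#' @export
print.capsnet_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %.2f%% (n = %d)\n", x$accuracy, x$n))
  cat("row-normalized confusion matrix (rows = truth):\n")
  print(round(x$normalized, 3))
  invisible(x)
}

#' Evaluate a fitted model on a labelled test set
#'
#' Predicts by argmax over the MLP logits in eval mode (or over the class
#' capsule lengths, the margin-path classifier useful for head-ablation
#' comparisons) and reports accuracy, per-class recall and the
#' (row-normalized) confusion matrix.
#'
#' @param model a fitted [capsnet()] model.
#' @param x feature matrix.
#' @param y true labels.
#' @param decision `"logits"` (default) or `"lengths"`.
#' @return a `capsnet_metrics` object.
#' @export
evaluate <- function(model, x, y, decision = c("logits", "lengths")) {
  decision <- match.arg(decision)
  if (!nrow(as.matrix(x))) stopf("test set must be non-empty")
  pred <- if (decision == "logits") predict(model, x, type = "class") else {
    lens <- predict(model, x, type = "lengths")
    factor(model$classes[max.col(lens)], levels = model$classes)
  }
  classification_metrics(factor(y, levels = model$classes), pred,
                         levels = model$classes)
}

make_folds <- function(y, n_folds, group = NULL) {
  n <- length(y)
  if (is.null(group)) {
    fold <- integer(n)
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  } else {
    g <- factor(group)
    if (nlevels(g) < n_folds) n_folds <- nlevels(g)
    gf <- setNames(rep(seq_len(n_folds), length.out = nlevels(g)),
                   sample(levels(g)))
    fold <- unname(gf[as.character(g)])
  }
  fold
}

#' Cross-validated training and evaluation
#'
#' Stratified (or group-wise, e.g. by subject or session) folds; features
#' are standardized and SMOTE-balanced inside each training fold only.
#' Reports per-fold accuracy, their mean and standard deviation, and the
#' confusion matrix aggregated over all folds.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param n_folds number of folds (default 5).
#' @param group optional grouping vector (e.g. subject or session ids);
#'   groups never straddle the train/test divide. With fewer groups than
#'   `n_folds` the fold count shrinks to the group count.
#' @param seed optional integer seed.
#' @param verbose print per-fold progress.
#' @param decision passed to [evaluate()]: classify from `"logits"`
#'   (default) or `"lengths"`.
#' @param ... passed to [capsnet()] (e.g. `epochs`, `alpha`).
#' @return an object of class `capsnet_cv`: `fold_accuracies`, `mean_acc`,
#'   `sd_acc`, aggregated `confusion`/`normalized`, per-fold `metrics` and
#'   `models`.
#' @export
capsnet_cv <- function(x, y, n_folds = 5L, group = NULL, seed = NULL,
                       verbose = FALSE, decision = "logits", ...) {
  if (!is_count(n_folds, 2L)) stopf("n_folds must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  yf <- factor(y)
  fold <- make_folds(as.integer(yf), n_folds, group)
  n_folds <- max(fold)
  lv <- levels(yf)
  conf <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  accs <- numeric(n_folds)
  metrics <- vector("list", n_folds)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    if (length(unique(yf[!te])) < length(lv))
      stopf("stratification error: fold %d lacks a class in training data", f)
    fit <- capsnet(x[!te, , drop = FALSE], yf[!te], ...)
    met <- evaluate(fit, x[te, , drop = FALSE], yf[te], decision = decision)
    accs[f] <- met$accuracy
    conf <- conf + met$confusion
    metrics[[f]] <- met
    models[[f]] <- fit
    if (verbose) message(sprintf("fold %d/%d: accuracy %.2f%%",
                                 f, n_folds, met$accuracy))
  }
  support <- rowSums(conf)
  structure(list(fold_accuracies = accs, mean_acc = mean(accs),
                 sd_acc = sd(accs), confusion = conf,
                 normalized = conf / ifelse(support == 0, 1, support),
                 metrics = metrics, models = models, fold = fold,
                 levels = lv),
            class = "capsnet_cv")
}

#' @export
print.capsnet_cv <- function(x, ...) {
  cat(sprintf("<capsnet_cv> %d folds: mean accuracy %.2f%% +/- %.2f%%\n",
              length(x$fold_accuracies), x$mean_acc, x$sd_acc))
  cat("fold accuracies:", paste(sprintf("%.2f", x$fold_accuracies),
                                collapse = ", "), "\n")
  cat("aggregated row-normalized confusion matrix:\n")
  print(round(x$normalized, 3))
  invisible(x)
}
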