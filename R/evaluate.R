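#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed as the tie-corrected Mann-Whitney
#' statistic: the probability that a random positive scores above a random
#' negative, with ties counting one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param truth Binary ground truth (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_mann_whitney(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
auc_mann_whitney <- function(scores, truth) {
  truth <- as.numeric(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate classifier scores against ground truth
#'
#' Computes the AUC (Mann-Whitney), plus accuracy, sensitivity and
#' specificity at the given decision threshold (score >= threshold is a
#' positive call), from the underlying confusion counts.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param truth Binary ground truth.
#' @param threshold Decision threshold (default 0.5).
#' @return A `classifier_metrics` object.
#' @export
classifier_metrics <- function(scores, truth, threshold = 0.5) {
  truth <- as.numeric(truth)
  auc <- auc_mann_whitney(scores, truth)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(
    auc = auc,
    accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    threshold = threshold,
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
    fold_aucs = NULL
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "Classifier metrics (threshold %.2f)\n  AUC %.3f | accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
    x$threshold, x$auc, x$accuracy, x$sensitivity, x$specificity))
  if (!is.null(x$fold_aucs)) {
    cat(sprintf("  %d-fold CV mean AUC %.3f\n", length(x$fold_aucs),
                mean(x$fold_aucs)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.classifier_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "accuracy", "sensitivity", "specificity"),
    value = c(x$auc, x$accuracy, x$sensitivity, x$specificity)
  )
}

#' @exportS3Method generics::glance
glance.classifier_metrics <- function(x, ...) {
  tibble::tibble(auc = x$auc, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 threshold = x$threshold,
                 mean_fold_auc = if (is.null(x$fold_aucs)) NA_real_ else
                   mean(x$fold_aucs))
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Partitions the rows into `k` class-stratified folds, trains the
#' multilayer perceptron on the remaining folds each time, and scores the
#' held-out fold. Reports pooled out-of-fold metrics plus the per-fold AUCs.
#'
#' @inheritParams train_mlp
#' @param k Number of folds (default 10).
#' @return A `classifier_metrics` with `fold_aucs`.
#' @export
cross_validate <- function(data, labels, k = 10, spec = mlp_spec(),
                           control = mlp_control(), seed = NULL) {
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(data), all(y %in% c(0, 1)), k >= 2)
  if (min(sum(y == 1), sum(y == 0)) < k) {
    stop("each class needs at least k rows for stratified folds", call. = FALSE)
  }
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in c(0, 1)) {
      rows <- which(y == cls)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fold_seeds <- sample.int(.Machine$integer.max, k)
    scores <- numeric(length(y))
    fold_aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- train_mlp(data[tr, , drop = FALSE], y[tr], spec = spec,
                       control = control, seed = fold_seeds[f])
      scores[fold == f] <<- mlp_forward(fit, data[!tr, , drop = FALSE])
      auc_mann_whitney(scores[fold == f], y[fold == f])
    }, numeric(1))
    out <- classifier_metrics(scores, y, threshold = spec$threshold)
    out$fold_aucs <- fold_aucs
    out
  })
}

#' ROC curve plot for classifier scores
#'
#' @param scores Numeric scores.
#' @param truth Binary ground truth.
#' @return A ggplot of the empirical ROC curve annotated with the AUC.
#' @export
plot_roc <- function(scores, truth) {
  truth <- as.numeric(truth)
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(truth[ord] == 1) / sum(truth == 1)
  fpr <- cumsum(truth[ord] == 0) / sum(truth == 0)
  df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- auc_mann_whitney(scores, truth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", auc)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}
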