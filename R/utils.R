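# Internal utilities: seed hygiene, classification metrics, stratified
# folds, and a small KNN classifier (no recommended-package dependency).

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels randomness through this,
# so nothing depends on hidden global state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one run seed (kept < 2^31).
.child_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-interpolated AP as used for precision-recall summaries:
#' AP = sum_n (R_n - R_{n-1}) P_n over descending score thresholds. The
#' chance level of a random scorer equals the positive-class prevalence.
#'
#' @param scores numeric classifier scores, higher = more positive
#' @param labels 0/1 (or logical) true labels
#' @return AP in [0, 1]
#' @export
average_precision <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / n_pos
  # collapse tied scores to the last (most permissive) cut within the tie
  last_of_tie <- c(sc[-length(sc)] != sc[-1], TRUE)
  precision <- precision[last_of_tie]
  recall <- recall[last_of_tie]
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with tie correction.
#'
#' @inheritParams average_precision
#' @return AUC in [0, 1]
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix and balanced accuracy
#'
#' @param truth,predicted vectors of class labels (coerced to a common
#'   factor; rows of the confusion matrix are true classes)
#' @return list: `confusion` (true x predicted counts), `balanced_accuracy`
#'   (mean per-class recall), `recall` (named per-class vector)
#' @export
confusion_report <- function(truth, predicted) {
  lev <- sort(unique(c(as.character(truth), as.character(predicted))))
  tt <- factor(truth, levels = lev)
  pp <- factor(predicted, levels = lev)
  cm <- table(truth = tt, predicted = pp)
  present <- rowSums(cm) > 0
  recall <- diag(as.matrix(cm))[present] / rowSums(cm)[present]
  list(confusion = cm, balanced_accuracy = mean(recall), recall = recall)
}

# Stratified fold assignment: each class is spread as evenly as possible
# across n_folds folds. Returns an integer fold id per observation.
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Stratified 70/30 split; returns list(train=, test=) of indices.
.stratified_split <- function(labels, train_frac = 0.7) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1, round(train_frac * length(idx)))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1
    train <- c(train, idx[sample.int(length(idx))][seq_len(n_tr)])
  }
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

# Minimal KNN classifier: majority vote among the k nearest training rows
# (Euclidean), first-level tie-break for determinism.
.knn_predict <- function(train_x, train_y, test_x, k) {
  train_y <- as.character(train_y)
  lev <- sort(unique(train_y))
  apply(test_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(factor(train_y[nn], levels = lev))
    lev[which.max(votes)]
  })
}

# z-score columns using train-set statistics (constant columns untouched).
.train_zscore <- function(train_x, test_x = NULL) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  z <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  list(train = z(train_x), test = if (!is.null(test_x)) z(test_x))
}
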