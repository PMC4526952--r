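# Stratified cross-validation and the evaluation suite: multiclass and
# top-k accuracy, one-vs-rest ROC (recall / precision / fall-out), AUC via
# the Mann-Whitney statistic, and the precision-recall break-even point.

#' Stratified fold assignment
#'
#' Within each class, items are shuffled (seeded) and dealt round-robin to
#' folds from a random starting fold, so per-class counts across folds
#' differ by at most one. Classes with fewer members than `k` leave some
#' folds without that class.
#'
#' @param labels category name per item.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..k`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("more folds than items", call. = FALSE)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k, 1L)
      fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
    }
  })
  fold
}

#' Exact-match multiclass accuracy
#'
#' @param predicted,truth equal-length category vectors.
#' @return fraction of exact matches.
#' @export
multiclass_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  mean(predicted == truth)
}

#' Top-k accuracy from a score matrix
#'
#' Fraction of items whose true category is among the `k` highest-scoring
#' categories; score ties break by category (column) order.
#'
#' @param scores score matrix, columns in scheme order.
#' @param truth category name per row.
#' @param k number of top categories considered (default 2).
#' @param scheme category scheme (defaults to the score column names).
#' @return fraction in [0, 1].
#' @export
topk_accuracy <- function(scores, truth, k = 2L, scheme = colnames(scores)) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > ncol(scores)) stop("k exceeds the number of categories", call. = FALSE)
  true_idx <- match(truth, scheme)
  hits <- vapply(seq_len(nrow(scores)), function(i) {
    ord <- order(-scores[i, ], seq_len(ncol(scores)))
    true_idx[i] %in% ord[seq_len(k)]
  }, logical(1L))
  mean(hits)
}

#' One-vs-rest ROC sweep
#'
#' Sweeps every distinct score as a threshold (prediction positive iff
#' score >= threshold) plus the all-negative endpoint, and reports recall
#' (true-positive rate), precision, and fall-out (false-positive rate) at
#' each. Precision is undefined (NA) when nothing is predicted positive.
#'
#' @param scores numeric per-item score for the class.
#' @param truth logical class membership per item.
#' @return tibble `threshold`, `recall`, `precision`, `fallout`, ordered by
#'   decreasing threshold (the all-negative endpoint first).
#' @export
roc_points <- function(scores, truth) {
  truth <- as.logical(truth)
  np <- sum(truth)
  nn <- sum(!truth)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present in truth", call. = FALSE)
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  rows <- lapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & truth)
    fp <- sum(pred & !truth)
    tibble::tibble(threshold = t, recall = tp / np,
                   precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
                   fallout = fp / nn)
  })
  dplyr::bind_rows(rows)
}

#' Area under the ROC curve
#'
#' Computed exactly as the Mann-Whitney statistic: the probability that a
#' random positive outscores a random negative, counting ties as one half.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, truth) {
  truth <- as.logical(truth)
  np <- sum(truth)
  nn <- sum(!truth)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present in truth", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision-recall break-even point
#'
#' Sweeps thresholds and returns the common value of precision and recall at
#' their crossing, as a percentage. When the curves cross between two sweep
#' points the crossing is linearly interpolated; the nearest sweep-point
#' value is attached as attribute `"nearest"`.
#'
#' @inheritParams roc_points
#' @return break-even percentage in [0, 100].
#' @export
break_even <- function(scores, truth) {
  truth <- as.logical(truth)
  if (sum(truth) == 0L) stop("no positive items", call. = FALSE)
  roc <- roc_points(scores, truth)
  roc <- roc[!is.na(roc$precision), ]
  d <- roc$precision - roc$recall
  i_near <- which.min(abs(d))
  nearest <- 100 * roc$recall[i_near] + 100 * (roc$precision[i_near] - roc$recall[i_near]) / 2
  value <- if (abs(d[i_near]) < 1e-12) {
    100 * roc$recall[i_near]
  } else {
    cross <- which(d[-length(d)] * d[-1L] < 0)
    if (length(cross) == 0L) {
      nearest
    } else {
      i <- cross[1L]
      t <- d[i] / (d[i] - d[i + 1L])
      100 * (roc$recall[i] + t * (roc$recall[i + 1L] - roc$recall[i]))
    }
  }
  attr(value, "nearest") <- nearest
  value
}

#' Stratified k-fold cross-validation of a classifier
#'
#' For each fold, `trainer` is fitted on the other folds and scores the
#' held-out items; the pooled predictions over all items yield the report.
#' Pretraining with unlabeled data is the caller's concern: pass a `trainer`
#' closure that starts fine-tuning from pretrained weights.
#'
#' @param X feature matrix.
#' @param y category name per row.
#' @param folds fold assignment from [stratified_folds()].
#' @param trainer function(`X_train`, `y_train`) returning a scoring
#'   function(`X_new`) -> score matrix with scheme-ordered columns.
#' @param scheme category scheme.
#' @return a `cv_report`: list with `scores` (pooled matrix), `predicted`,
#'   `accuracy` (pooled), `per_fold` (tibble `fold`, `accuracy`),
#'   `top2_accuracy`, `per_class` (tibble `category`, `auc`, `break_even`),
#'   `confusion` (truth x predicted matrix), `folds`.
#' @export
cross_validate <- function(X, y, folds, trainer, scheme = category_scheme()) {
  stopifnot(nrow(X) == length(y), length(folds) == length(y))
  k <- max(folds)
  scores <- matrix(NA_real_, nrow(X), length(scheme),
                   dimnames = list(NULL, scheme))
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    missing_classes <- setdiff(unique(y[test_idx]), unique(y[train_idx]))
    if (length(missing_classes) > 0L) {
      warning(sprintf("fold %d training data lacks class(es): %s",
                      f, paste(missing_classes, collapse = ", ")))
    }
    score_fun <- trainer(X[train_idx, , drop = FALSE], y[train_idx])
    scores[test_idx, ] <- score_fun(X[test_idx, , drop = FALSE])
  }
  predicted <- assign_categories(scores, scheme)
  per_fold <- tibble::tibble(
    fold = seq_len(k),
    accuracy = vapply(seq_len(k), function(f) {
      idx <- which(folds == f)
      multiclass_accuracy(predicted[idx], y[idx])
    }, numeric(1L))
  )
  per_class <- dplyr::bind_rows(lapply(scheme, function(cls) {
    is_cls <- y == cls
    if (sum(is_cls) == 0L || sum(!is_cls) == 0L) {
      return(tibble::tibble(category = cls, auc = NA_real_,
                            break_even = NA_real_))
    }
    tibble::tibble(category = cls,
                   auc = auc_score(scores[, cls], is_cls),
                   break_even = as.numeric(break_even(scores[, cls], is_cls)))
  }))
  confusion <- table(factor(y, levels = scheme),
                     factor(predicted, levels = scheme))
  structure(
    list(scores = scores, predicted = predicted,
         accuracy = multiclass_accuracy(predicted, y),
         per_fold = per_fold,
         top2_accuracy = topk_accuracy(scores, y, k = min(2L, length(scheme)),
                                       scheme = scheme),
         per_class = per_class, confusion = confusion, folds = folds),
    class = "cv_report"
  )
}
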