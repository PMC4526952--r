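# Stratified folds, cross-validation, and the metric suite.

test_that("stratified folds balance classes and honor the seed", {
  labels <- rep(c("Other", "Misuse"), each = 10L)
  f <- stratified_folds(labels, k = 10L, seed = 1L)
  tab <- table(labels, f)
  expect_true(all(tab == 1L))

  # a 7-member class lands in exactly 7 distinct folds
  labels2 <- c(rep("Other", 40L), rep("Misuse", 7L))
  f2 <- stratified_folds(labels2, k = 10L, seed = 2L)
  expect_identical(length(unique(f2[labels2 == "Misuse"])), 7L)

  expect_identical(stratified_folds(labels2, 10L, seed = 9L),
                   stratified_folds(labels2, 10L, seed = 9L))
  expect_error(stratified_folds(c("a", "b"), k = 10L, seed = 1L), "folds")
})

test_that("per-class fold counts never differ by more than one", {
  set.seed(3)
  for (rep_ in 1:3) {
    labels <- sample(category_scheme(), 97L, TRUE,
                     prob = prop.table(c(21, 88, 28, 38, 72, 132, 16, 15, 7)))
    f <- stratified_folds(labels, k = 10L, seed = rep_)
    tab <- table(labels, f)
    expect_true(all(apply(tab, 1L, function(r) diff(range(r))) <= 1L))
  }
})

test_that("multiclass accuracy is the exact-match fraction", {
  expect_identical(multiclass_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_identical(multiclass_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_error(multiclass_accuracy("a", c("a", "b")), "equal length")
  # 293 of 416 correct reproduces the headline cross-validation ratio
  truth <- rep("x", 416L)
  pred <- c(rep("x", 293L), rep("y", 123L))
  expect_equal(100 * multiclass_accuracy(pred, truth), 70.4, tolerance = 0.05)
})

test_that("cross-validation pools predictions over folds", {
  labels <- rep(category_scheme()[1:2], each = 20L)
  X <- matrix(0, 40L, 2L)
  folds <- stratified_folds(labels, 5L, seed = 1L)
  perfect <- function(X_tr, y_tr) {
    ids <- seq_len(nrow(X))
    function(X_new) {
      P <- matrix(1e-6, nrow(X_new), 9L, dimnames = list(NULL, category_scheme()))
      # recover each row's identity via its row index stored in column 1
      for (i in seq_len(nrow(X_new))) {
        P[i, labels[X_new[i, 1L]]] <- 1 - 8e-6
      }
      P
    }
  }
  X[, 1L] <- seq_len(40L)
  cv <- cross_validate(X, labels, folds, perfect)
  expect_identical(cv$accuracy, 1)
  expect_true(all(cv$per_fold$accuracy == 1))
  expect_identical(sum(cv$confusion), 40L)
})

test_that("a majority-class stub attains the base-rate accuracy on the printed class counts", {
  counts <- c(21L, 88L, 28L, 38L, 72L, 132L, 16L, 15L, 7L)
  labels <- rep(category_scheme(), counts)
  X <- matrix(0, length(labels), 3L)
  folds <- stratified_folds(labels, 10L, seed = 4L)
  cv <- suppressWarnings(
    cross_validate(X, labels, folds, constant_trainer("Resistance")))
  expect_equal(cv$accuracy, 132 / sum(counts), tolerance = 1e-12)
  # confusion matrix rows recover the class counts
  expect_equal(unname(rowSums(cv$confusion)), as.numeric(counts))
})

test_that("top-k accuracy handles ties by category order and recovers argmax at k = 1", {
  scores <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.4, 0.4), c(1 / 3, 1 / 3, 1 / 3))
  colnames(scores) <- c("a", "b", "c")
  expect_identical(topk_accuracy(scores, c("a", "b", "c"), k = 3L), 1)
  truth <- c("a", "b", "a")
  argmax_pred <- colnames(scores)[max.col(scores, ties.method = "first")]
  expect_identical(topk_accuracy(scores, truth, k = 1L),
                   multiclass_accuracy(argmax_pred, truth))
  # row 2: scores tie at 0.4; category order ranks "b" before "c"
  expect_identical(topk_accuracy(scores[2L, , drop = FALSE], "c", k = 1L), 0)
  expect_identical(topk_accuracy(scores[2L, , drop = FALSE], "b", k = 1L), 1)
  expect_error(topk_accuracy(scores, c("a", "b", "c"), k = 0L), "at least 1")
  # the printed evaluation-set top-2 ratio
  expect_equal(100 * 158 / 246, 64.2, tolerance = 0.05)
})

test_that("ROC sweep matches a hand enumeration", {
  scores <- c(0.9, 0.4, 0.5, 0.1)
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- roc_points(scores, truth)
  expect_identical(roc$threshold, c(Inf, 0.9, 0.5, 0.4, 0.1))
  expect_equal(roc$recall, c(0, 0.5, 0.5, 1, 1))
  expect_equal(roc$fallout, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$precision, c(NA, 1, 0.5, 2 / 3, 0.5))

  # perfectly separating scores contain the ideal corner
  roc2 <- roc_points(c(0.9, 0.8, 0.2, 0.1), truth)
  expect_true(any(roc2$recall == 1 & roc2$fallout == 0))

  # all-equal scores: a single non-endpoint sweep point with recall 1, fall-out 1
  roc3 <- roc_points(rep(0.3, 4L), truth)
  expect_identical(nrow(roc3), 2L)
  expect_equal(roc3$recall[2L], 1)
  expect_equal(roc3$fallout[2L], 1)

  expect_error(roc_points(scores, rep(TRUE, 4L)), "both classes")
})

test_that("AUC equals the Mann-Whitney statistic", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  expect_identical(auc_score(c(0.9, 0.8, 0.2, 0.1), truth), 1)
  expect_identical(auc_score(rep(0.5, 4L), truth), 0.5)
  expect_identical(auc_score(c(0.9, 0.4, 0.5, 0.1), truth), 0.75)
  expect_error(auc_score(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("trapezoidal ROC area equals Mann-Whitney AUC on random instances", {
  set.seed(42)
  for (rep_ in 1:200) {
    n <- sample(6:40, 1L)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, TRUE))
    scores <- round(runif(n), sample(c(1L, 2L, 7L), 1L))  # force some ties
    expect_equal(oracle_auc_trapezoid(roc_points(scores, truth)),
                 auc_score(scores, truth), tolerance = 1e-9)
  }
})

test_that("recall and fall-out are non-increasing in the threshold", {
  set.seed(5)
  scores <- runif(50L)
  truth <- rbinom(50L, 1L, 0.4) == 1L
  roc <- roc_points(scores, truth)  # ordered by decreasing threshold
  expect_true(all(diff(roc$recall) >= 0))
  expect_true(all(diff(roc$fallout) >= 0))
})

test_that("random scores on a large sample give chance-level AUC", {
  set.seed(77)
  scores <- runif(2000L)
  truth <- rbinom(2000L, 1L, 0.5) == 1L
  expect_lt(abs(auc_score(scores, truth) - 0.5), 0.03)
})

test_that("break-even point interpolates the precision-recall crossing", {
  # perfect classifier
  expect_equal(as.numeric(break_even(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE))), 100)
  # hand sweep: crossing sits at precision = recall = 0.5
  expect_equal(as.numeric(break_even(c(0.9, 0.6, 0.7, 0.2),
                                     c(TRUE, TRUE, FALSE, FALSE))), 50)
  # single positive holding the top score
  expect_equal(as.numeric(break_even(c(0.9, 0.3, 0.2), c(TRUE, FALSE, FALSE))), 100)
  expect_error(break_even(c(0.2, 0.3), c(FALSE, FALSE)), "no positive")
})
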