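#!/usr/bin/env Rscript
# Step 5: semi-supervised training and cross-validated evaluation.
#
# Pretrains a stack of RBMs on unlabeled tweets, fine-tunes on the
# adjudicated labels, and evaluates by stratified 10-fold CV: pooled
# accuracy, top-2 accuracy, and per-class AUC / break-even. Desk-scale
# network (60/60/30 hidden units) and epochs so the whole step runs in
# two to three minutes.

library(tweetdbn)

seed <- 1L
store <- read_tweets_jsonl("results/corpus.jsonl")
labels <- read.csv("results/labels.csv", colClasses = "character")
X <- readRDS("scratch/features.rds")

lab_idx <- match(labels$tweet_id, store$id)
Xl <- X[lab_idx, ]
yl <- labels$category
unlab_idx <- withr::with_seed(seed + 3L, sample.int(nrow(store), 3000L))

sizes <- c(ncol(X), 60L, 60L, 30L, length(category_scheme()))
pre <- pretrain_dbn(X[unlab_idx, ], sizes,
                    pretrain_config(epochs_per_layer = 5L, seed = seed + 4L))
fin <- finetune_config(epochs = 120L, seed = seed + 5L)

folds <- stratified_folds(yl, k = 10L, seed = seed + 6L)
trainer <- function(X_tr, y_tr) {
  m <- finetune_dbn(pre, X_tr, y_tr, fin)
  function(X_new) predict_scores(m, X_new)
}
cv <- suppressWarnings(cross_validate(Xl, yl, folds, trainer))
write.csv(cv$per_fold, "results/cv_report.csv", row.names = FALSE)
write.csv(cv$per_class, "results/per_class.csv", row.names = FALSE)
write.csv(as.data.frame.matrix(cv$confusion), "results/confusion.csv")

cat(sprintf("Pooled 10-fold CV accuracy: %.1f%% (%d/%d); top-2: %.1f%%.\n",
            100 * cv$accuracy, round(cv$accuracy * nrow(Xl)), nrow(Xl),
            100 * cv$top2_accuracy))
cat("Per-class one-vs-rest evaluation:\n")
for (i in seq_len(nrow(cv$per_class))) {
  cat(sprintf("  %-20s AUC %.2f  break-even %s\n",
              cv$per_class$category[i], cv$per_class$auc[i],
              ifelse(is.na(cv$per_class$break_even[i]), "-",
                     sprintf("%.0f", cv$per_class$break_even[i]))))
}

final <- finetune_dbn(pre, Xl, yl, fin)
save_dbn(final, "results/model.json")
cat("Final model (trained on all labels) written to results/model.json\n")
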