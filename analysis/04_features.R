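#!/usr/bin/env Rscript
# Step 4: bag-of-stems feature engineering.
#
# Builds the class-informed vocabulary (top stems per class plus top stems
# overall), freezes the feature layout (stem-presence bits + 10 length bins
# + URL flag), and encodes every tweet.

library(tweetdbn)

store <- read_tweets_jsonl("results/corpus.jsonl")
labels <- read.csv("results/labels.csv", colClasses = "character")

lab_idx <- match(labels$tweet_id, store$id)
vocab <- build_vocabulary(store$text[lab_idx], labels$category, store$text,
                          per_class_top = 50L, overall_top = 1000L)
fs <- feature_spec(vocab)
write_feature_spec(fs, "results/feature_spec.json")

X <- featurize_tweets(store, fs)
cat(sprintf("Vocabulary: %d stems (per-class top 50 + overall top 1000).\n",
            length(fs$stems)))
cat(sprintf("Feature layout: %d stems + 10 length bins + URL flag = %d dims.\n",
            length(fs$stems), fs$total_dim))
cat(sprintf("Encoded %d tweets; mean active bits/tweet: %.1f.\n",
            nrow(X), mean(rowSums(X))))
saveRDS(X, "scratch/features.rds")  # dense matrix cache for steps 5-6
cat("Wrote results/feature_spec.json and scratch/features.rds\n")
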