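#!/usr/bin/env Rscript
# Step 1: simulate the study corpus.
#
# Generates a 60-day synthetic antibiotic tweet stream under the package's
# default study conditions (Poisson volume with one five-fold spike on day
# 30, nine topic categories with the uneven labeled-set prior, Zipf hashtags
# and users, retweet fraction 0.279), plus three simulated raters over a
# 1000-tweet sample (the same rating budget the original study used).
# Writes the corpus and label files consumed by the later steps.

library(tweetdbn)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
gen <- generate_corpus(cfg)
write_tweets_jsonl(gen$store, "results/corpus.jsonl")
write.csv(gen$truth, "results/truth.csv", row.names = FALSE)

sample_ids <- withr::with_seed(seed + 1L, sample(gen$truth$tweet_id, 1000L))
truth_sample <- gen$truth[gen$truth$tweet_id %in% sample_ids, ]
votes <- generate_rater_table(truth_sample, n_raters = 3L,
                              agreement = cfg$rater_agreement,
                              seed = seed + 2L)
write_votes_csv(votes, "results/votes.csv")

cat(sprintf("Simulated %d tweets over %d days (%.1f/day); %.1f%% retweets.\n",
            nrow(gen$store), cfg$n_days, nrow(gen$store) / cfg$n_days,
            100 * mean(is_retweet(gen$store))))
cat(sprintf("Rated sample: %d tweets x 3 raters at agreement %.2f.\n",
            nrow(truth_sample), cfg$rater_agreement))
cat("Wrote results/corpus.jsonl, results/truth.csv, results/votes.csv\n")
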