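#!/usr/bin/env Rscript
# Step 2: query-style characterization of the corpus.
#
# Daily volume with Z-score spike detection, hashtag usage, user
# concentration, and retweet structure — the in-memory equivalents of the
# warehouse queries used to describe the original stream.

library(tweetdbn)

store <- read_tweets_jsonl("results/corpus.jsonl")

series <- daily_counts(store)
write.csv(series, "results/daily_counts.csv", row.names = FALSE)
sp <- zscore_spikes(series, threshold = 2.0)
write.csv(sp$days, "results/spikes.csv", row.names = FALSE)
cat(sprintf("Mean %.1f tweets/day (SD %.1f); %d day(s) above Z = 2.0: %s\n",
            sp$mean, sp$sd, nrow(sp$flagged),
            paste(sp$flagged$date, collapse = ", ")))

for (d in sp$flagged$date) {
  top <- top_stems_for_day(store, as.Date(d, origin = "1970-01-01"), k = 5L)
  cat(sprintf("  top stems on %s: %s\n", as.Date(d, origin = "1970-01-01"),
              paste(sprintf("%s (%d)", top$stem, top$count), collapse = ", ")))
}

ht <- hashtag_stats(store)
write.csv(ht$table, "results/hashtags.csv", row.names = FALSE)
cat(sprintf("%d distinct hashtags, %d usages; %.2f%% used < 100 times.\n",
            ht$n_distinct, ht$total_usages, 100 * ht$n_rare / max(ht$n_distinct, 1L)))
cat(sprintf("  top tags: %s\n",
            paste(sprintf("#%s %d (%.1f%%)", head(ht$table$tag, 5L),
                          head(ht$table$count, 5L),
                          100 * head(ht$table$rel_freq, 5L)), collapse = ", ")))

uc <- user_concentration(store, min_tweets = 10L)
write.csv(uc$per_user, "results/users.csv", row.names = FALSE)
cat(sprintf("%d users; %d heavy users (>= 10 tweets) hold %.2f%% of tweets.\n",
            uc$n_users, uc$n_heavy_users, 100 * uc$heavy_user_share))

rs <- retweet_summary(store, viral_cutoff = 50L)
write.csv(rs$tallies, "results/retweets.csv", row.names = FALSE)
cat(sprintf("%.2f%% retweets (%d/%d); %d message(s) retweeted > 50 times.\n",
            100 * rs$fraction, rs$n_retweets, rs$total, rs$n_viral))
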