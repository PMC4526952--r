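#!/usr/bin/env Rscript
# Step 3: rater agreement and label adjudication.
#
# Fleiss' kappa over the three simulated raters, then 2-of-3 majority
# adjudication into the labeled set used for classifier training.

library(tweetdbn)

votes <- read_votes_csv("results/votes.csv")
kappa <- fleiss_kappa(votes)
adj <- adjudicate(votes, min_agree = 2L)
write.csv(adj$labels, "results/labels.csv", row.names = FALSE)
write.csv(data.frame(tweet_id = adj$dropped), "results/dropped.csv",
          row.names = FALSE)

cat(sprintf("Fleiss' kappa over %d items x 3 raters: %.3f\n",
            length(unique(votes$tweet_id)), kappa))
cat(sprintf("Adjudication kept %d tweets, dropped %d (no 2-of-3 majority).\n",
            nrow(adj$labels), length(adj$dropped)))
tab <- table(adj$labels$category)[category_scheme()]
cat("Label distribution:\n")
for (cl in category_scheme()) {
  cat(sprintf("  %-20s %d\n", cl, ifelse(is.na(tab[cl]), 0L, tab[cl])))
}
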