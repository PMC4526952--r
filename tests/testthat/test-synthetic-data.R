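# Synthetic corpus generator: degenerate cases, distributional checks,
# determinism, and the simulated rater table.

no_spikes <- data.frame(day = integer(0), multiplier = numeric(0))

test_that("zero-rate configuration yields an empty corpus and label map", {
  cfg <- generator_config(n_days = 1L, base_rate = 0, spike_days = no_spikes)
  gen <- generate_corpus(cfg)
  expect_identical(nrow(gen$store), 0L)
  expect_identical(nrow(gen$truth), 0L)
})

test_that("an injected spike day dominates every other day's count", {
  cfg <- generator_config(n_days = 30L, base_rate = 100,
                          spike_days = data.frame(day = 10L, multiplier = 5),
                          seed = 7L)
  gen <- generate_corpus(cfg)
  counts <- daily_counts(gen$store)$count
  expect_identical(length(counts), 30L)
  expect_true(counts[11L] > max(counts[-11L]))
})

test_that("category fractions track a uniform prior within 4 standard errors", {
  cfg <- generator_config(n_days = 10L, base_rate = 200,
                          spike_days = no_spikes,
                          category_prior = rep(1 / 9, 9), retweet_prob = 0,
                          seed = 3L)
  gen <- generate_corpus(cfg)
  n <- nrow(gen$truth)
  frac <- table(factor(gen$truth$category, levels = category_scheme())) / n
  se <- sqrt((1 / 9) * (8 / 9) / n)
  expect_true(all(abs(frac - 1 / 9) < 4 * se))
})

test_that("every tweet's text contains a signature stem of its category", {
  cfg <- generator_config(n_days = 3L, base_rate = 80, spike_days = no_spikes,
                          seed = 5L)
  gen <- generate_corpus(cfg)
  sig <- tweetdbn:::default_signature_vocab()
  cat_of <- gen$truth$category[match(gen$store$id, gen$truth$tweet_id)]
  ok <- vapply(seq_len(nrow(gen$store)), function(i) {
    toks <- strsplit(sub("^RT @[^:]*: ", "", gen$store$text[i]), " ")[[1L]]
    any(toks %in% sig[[cat_of[i]]])
  }, logical(1L))
  expect_true(all(ok))
})

test_that("identical config and seed give a byte-identical serialized corpus", {
  cfg <- generator_config(n_days = 5L, base_rate = 50, seed = 11L,
                          spike_days = data.frame(day = 2L, multiplier = 3))
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_tweets_jsonl(generate_corpus(cfg)$store, f1)
  write_tweets_jsonl(generate_corpus(cfg)$store, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0L)
})

test_that("total tweet count equals the sum of per-day counts", {
  gen <- generate_corpus(generator_config(n_days = 12L, base_rate = 40, seed = 2L,
                                          spike_days = no_spikes))
  expect_identical(nrow(gen$store), sum(gen$day_counts))
  expect_identical(sum(daily_counts(gen$store)$count), nrow(gen$store))
})

test_that("retweet fraction converges to the configured probability", {
  cfg <- generator_config(n_days = 60L, base_rate = 200, spike_days = no_spikes,
                          retweet_prob = 0.25, seed = 13L)
  gen <- generate_corpus(cfg)
  n <- nrow(gen$store)
  expect_gte(n, 10000L)
  frac <- mean(is_retweet(gen$store))
  expect_lt(abs(frac - 0.25), 4 * sqrt(0.25 * 0.75 / n))
})

test_that("hashtag usage is non-increasing in hashtag rank", {
  cfg <- generator_config(n_days = 30L, base_rate = 300, spike_days = no_spikes,
                          hashtag_prob = 0.8, seed = 17L)
  gen <- generate_corpus(cfg)
  ht <- hashtag_stats(gen$store)
  vocab <- tweetdbn:::default_hashtag_vocab()
  counts <- ht$table$count[match(vocab, ht$table$tag)]
  counts[is.na(counts)] <- 0L
  # expected counts are proportional to rank^(-1); check widely separated ranks
  expect_gt(counts[1L], counts[5L])
  expect_gt(counts[5L], counts[50L])
})

test_that("invalid configurations name the offending field", {
  expect_error(generator_config(n_days = 0L), "n_days")
  expect_error(generator_config(spike_days = data.frame(day = 99L, multiplier = 2)),
               "spike_days")
  expect_error(generator_config(category_prior = rep(0.5, 9)), "category_prior")
  expect_error(generator_config(retweet_prob = 1.5), "retweet_prob")
  sig <- tweetdbn:::default_signature_vocab()
  sig[["Misuse"]][1L] <- sig[["Animals"]][1L]
  expect_error(generator_config(signature_vocab = sig), "signature_vocab")
})

test_that("simulated raters at full agreement always match the truth", {
  truth <- tibble::tibble(tweet_id = sprintf("t%03d", 1:40),
                          category = sample(category_scheme(), 40, TRUE))
  votes <- generate_rater_table(truth, n_raters = 3L, agreement = 1, seed = 1L)
  expect_identical(nrow(votes), 120L)
  merged <- merge(votes, truth, by = "tweet_id")
  expect_true(all(merged$category.x == merged$category.y))
  expect_equal(fleiss_kappa(votes), 1.0)
})

test_that("per-rater empirical accuracy tracks the agreement parameter", {
  set.seed(42)
  truth <- tibble::tibble(tweet_id = sprintf("t%03d", 1:500),
                          category = sample(category_scheme(), 500, TRUE))
  votes <- generate_rater_table(truth, n_raters = 3L, agreement = 0.8, seed = 9L)
  se <- sqrt(0.8 * 0.2 / 500)
  for (r in unique(votes$rater_id)) {
    v <- votes[votes$rater_id == r, ]
    acc <- mean(v$category == truth$category[match(v$tweet_id, truth$tweet_id)])
    expect_lt(abs(acc - 0.8), 4 * se)
  }
})

test_that("rater simulation rejects an empty label map", {
  empty <- tibble::tibble(tweet_id = character(0), category = character(0))
  expect_error(generate_rater_table(empty, 3L, 0.8, seed = 1L), "empty")
})
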