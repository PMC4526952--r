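# Tokenization, vocabulary construction, and binary featurization.

test_that("tokenizer lowercases, strips URLs/mentions/#, and drops stopwords", {
  expect_identical(tokenize_text("Antibiotic-resistant superbugs!")[[1L]],
                   c("antibiotic", "resistant", "superbugs"))
  expect_identical(tokenize_text("RT @USERID: 80% of all antibiotics")[[1L]],
                   c("80", "antibiotics"))
  expect_identical(tokenize_text("")[[1L]], character(0))
  expect_identical(tokenize_text("see https://t.co/abc #news now")[[1L]],
                   c("see", "news", "now"))
})

test_that("vocabulary takes per-class top stems plus overall top stems, deduplicated", {
  texts <- c("aaa aaa bbb", "aaa ccc", "bbb aaa")
  labels <- rep("Other", 3L)
  v <- suppressWarnings(build_vocabulary(texts, labels, all_texts = character(0),
                                         per_class_top = 2L, overall_top = 0L))
  expect_identical(v$stems, c("aaa", "bbb"))

  # a stem in two classes' top lists appears once
  texts2 <- c("xxx yyy", "xxx zzz")
  labels2 <- c("Other", "Misuse")
  v2 <- suppressWarnings(build_vocabulary(texts2, labels2, all_texts = character(0),
                                          per_class_top = 2L))
  expect_identical(anyDuplicated(v2$stems), 0L)
  expect_true("xxx" %in% v2$stems)

  # a class with fewer distinct stems than the cap contributes no padding
  v3 <- suppressWarnings(build_vocabulary("solo", "Other", all_texts = character(0),
                                          per_class_top = 50L, overall_top = 0L))
  expect_identical(v3$stems, "solo")
})

test_that("frequency ties break by stem ascending and order is input-invariant", {
  texts <- c("zeta alpha", "zeta alpha", "beta beta")
  labels <- rep("Other", 3L)
  v <- suppressWarnings(build_vocabulary(texts, labels, all_texts = character(0),
                                         per_class_top = 2L, overall_top = 0L))
  # counts: zeta 2, alpha 2, beta 2 -> top-2 alphabetical among ties
  expect_identical(v$stems, c("alpha", "beta"))
  set.seed(1)
  perm <- sample(3L)
  v_shuffled <- suppressWarnings(build_vocabulary(texts[perm], labels[perm],
                                                  all_texts = character(0),
                                                  per_class_top = 2L, overall_top = 0L))
  expect_identical(v$stems, v_shuffled$stems)
})

test_that("featurize sets bag bits, exactly one length bin, and the URL flag", {
  spec <- feature_spec(c("antibiot", "resist", "doctor", "farm", "lol"))
  expect_identical(spec$total_dim, 16L)
  text47 <- paste(rep("resist", 6), collapse = " ")  # 41 chars
  text47 <- paste0(text47, " abcde")                 # 47 chars
  store <- make_store(c(text47, strrep("x", 140), "doctor visit"),
                      has_url = c(FALSE, FALSE, TRUE))
  X <- featurize_tweets(store, spec)
  expect_identical(dim(X), c(3L, 16L))
  # stem presence
  expect_identical(unname(X[1L, 1:5]), c(0, 1, 0, 0, 0))
  expect_identical(unname(X[3L, 1:5]), c(0, 0, 1, 0, 0))
  # length bins: 47 -> bin index 4 (0-based), 140 clamps to bin 9
  expect_identical(unname(X[1L, 5L + 1:10]), as.numeric(seq(0, 9) == 4))
  expect_identical(unname(X[2L, 5L + 1:10]), as.numeric(seq(0, 9) == 9))
  expect_identical(unname(X[, 16L]), c(0, 0, 1))
  # exactly one length-bin bit per row
  expect_identical(unname(rowSums(X[, 6:15])), rep(1, 3))
})

test_that("a 1372-stem vocabulary yields the canonical 1383 dimensions", {
  spec <- feature_spec(sprintf("s%04d", 1:1372))
  expect_identical(spec$total_dim, 1383L)
})

test_that("every bag column is supported by the corpus that built the vocabulary", {
  gen <- generate_corpus(generator_config(n_days = 3L, base_rate = 80, seed = 31L,
                                          spike_days = data.frame(day = integer(0),
                                                                  multiplier = numeric(0))))
  y <- gen$truth$category[match(gen$store$id, gen$truth$tweet_id)]
  v <- build_vocabulary(gen$store$text, y, gen$store$text,
                        per_class_top = 10L, overall_top = 50L)
  X <- featurize_tweets(gen$store, feature_spec(v))
  expect_true(all(colSums(X[, seq_along(v$stems), drop = FALSE]) >= 1))
})

test_that("one length-bin bit per row holds on random corpora", {
  for (seed in c(5L, 6L)) {
    gen <- generate_corpus(generator_config(n_days = 2L, base_rate = 50, seed = seed,
                                            spike_days = data.frame(day = integer(0),
                                                                    multiplier = numeric(0))))
    spec <- feature_spec(c("antibiot", "resist"))
    X <- featurize_tweets(gen$store, spec)
    expect_true(all(rowSums(X[, 3:12, drop = FALSE]) == 1))
  }
})

test_that("feature specs survive a JSON round trip", {
  spec <- feature_spec(c("antibiot", "resist", "doctor"))
  f <- withr::local_tempfile(fileext = ".json")
  write_feature_spec(spec, f)
  back <- read_feature_spec(f)
  expect_identical(back$stems, spec$stems)
  expect_identical(back$total_dim, spec$total_dim)
  writeLines("{}", f)
  expect_error(read_feature_spec(f), "format")
})
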