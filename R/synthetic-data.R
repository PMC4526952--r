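# Seeded synthetic tweet-stream generator.
#
# Emulates the statistical structure the downstream analyses assume: Poisson
# daily volume with injected spike days, class-conditional signature
# vocabulary over nine topic categories, Zipf-distributed hashtags and user
# activity, a retweet fraction, and per-category URL probability. Texts are
# space-joined sequences of already-stemmed tokens, so the feature stage's
# stemmer acts as the identity on synthetic text.

default_signature_vocab <- function() {
  list(
    "Advertisement"      = c("promo", "discount", "coupon", "pharmaci", "generic", "order"),
    "Advice/Information" = c("advic", "doctor", "inform", "prescript", "dose", "health"),
    "Animals"            = c("farm", "cattl", "livestock", "chicken", "anim", "poultri"),
    "General use"        = c("strep", "throat", "infect", "sick", "penicillin", "bronchit"),
    "Other"              = c("piper", "joke", "lol", "word", "school", "meme"),
    "Resistance"         = c("resist", "superbug", "bacteria", "mrsa", "drug", "combat"),
    "Side effects"       = c("stomach", "nausea", "rash", "hurt", "vomit", "dizzi"),
    "Wanting/Needing"    = c("want", "need", "wait", "tomorrow", "appoint", "doc"),
    "Misuse"             = c("leftov", "mix", "alcohol", "share", "skip", "vicodin")
  )
}

default_background_vocab <- function() {
  real <- c("antibiot", "take", "day", "get", "go", "feel", "week", "time",
            "today", "still", "amoxicillin", "pill", "med", "start", "work",
            "bad", "good", "now", "back", "help", "new", "think", "know",
            "look", "come", "peopl", "year", "use", "right", "thing")
  c(real, sprintf("w%03d", seq_len(170) + 30L))
}

default_hashtag_vocab <- function() {
  named <- c("antibiotics", "antibiotic", "health", "longitudeprize",
             "penicillin", "antibioticresistance", "news", "saveabx")
  c(named, sprintf("tag%03d", seq_len(292) + 8L))
}

#' Configuration for the synthetic tweet generator
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: a 60-day collection with one five-fold spike day, an
#' uneven nine-category prior matching the labeled-set distribution, a
#' retweet fraction of 0.279, and Zipf-distributed hashtag and user
#' activity.
#'
#' @param n_days number of calendar days.
#' @param base_rate expected tweets per day (Poisson mean).
#' @param spike_days data frame with columns `day` (0-based index) and
#'   `multiplier`; `NULL` (the default) injects one five-fold spike halfway
#'   through the window. Use a zero-row data frame for no spikes.
#' @param category_prior probability vector over the scheme's categories.
#' @param signature_vocab named list of per-category signature stems
#'   (pairwise disjoint).
#' @param background_vocab ranked background stem list.
#' @param background_zipf_exponent Zipf exponent for background stems.
#' @param signature_rate probability that each additional token is a
#'   signature stem rather than background.
#' @param tokens_per_tweet integer (min, max) tokens per tweet.
#' @param hashtag_prob probability a tweet carries a hashtag.
#' @param hashtag_vocab ranked hashtag list.
#' @param hashtag_zipf_exponent Zipf exponent for hashtags.
#' @param n_users number of distinct users.
#' @param user_zipf_exponent Zipf exponent for user activity.
#' @param retweet_prob probability a tweet is a retweet of an earlier one.
#' @param url_prob_per_category named per-category URL probability.
#' @param rater_agreement default probability a simulated rater reports the
#'   true category.
#' @param scheme category scheme.
#' @param seed integer seed; the corpus is reproducible given the config.
#' @return validated `generator_config` list.
#' @export
generator_config <- function(n_days = 60L,
                             base_rate = 100,
                             spike_days = NULL,
                             category_prior = prop.table(c(21, 88, 28, 38, 72, 132, 16, 15, 7)),
                             signature_vocab = default_signature_vocab(),
                             background_vocab = default_background_vocab(),
                             background_zipf_exponent = 1.1,
                             signature_rate = 0.25,
                             tokens_per_tweet = c(5L, 12L),
                             hashtag_prob = 0.39,
                             hashtag_vocab = default_hashtag_vocab(),
                             hashtag_zipf_exponent = 1.0,
                             n_users = 3000L,
                             user_zipf_exponent = 1.0,
                             retweet_prob = 0.279,
                             url_prob_per_category = c(0.9, 0.7, 0.5, 0.2, 0.3,
                                                       0.6, 0.15, 0.1, 0.1),
                             rater_agreement = 0.8,
                             scheme = category_scheme(),
                             seed = 1L) {
  if (is.null(spike_days)) {
    # one five-fold spike halfway through the collection window
    spike_days <- data.frame(day = as.integer(n_days) %/% 2L, multiplier = 5)
  }
  cfg <- list(n_days = as.integer(n_days), base_rate = base_rate,
              spike_days = spike_days, category_prior = category_prior,
              signature_vocab = signature_vocab,
              background_vocab = background_vocab,
              background_zipf_exponent = background_zipf_exponent,
              signature_rate = signature_rate,
              tokens_per_tweet = as.integer(tokens_per_tweet),
              hashtag_prob = hashtag_prob, hashtag_vocab = hashtag_vocab,
              hashtag_zipf_exponent = hashtag_zipf_exponent,
              n_users = as.integer(n_users),
              user_zipf_exponent = user_zipf_exponent,
              retweet_prob = retweet_prob,
              url_prob_per_category = url_prob_per_category,
              rater_agreement = rater_agreement, scheme = scheme,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_days < 1L) stop_config("n_days", "must be >= 1")
  if (cfg$base_rate < 0) stop_config("base_rate", "must be >= 0")
  if (nrow(cfg$spike_days) > 0) {
    if (any(cfg$spike_days$day < 0L | cfg$spike_days$day >= cfg$n_days)) {
      stop_config("spike_days", "has a day index outside [0, n_days)")
    }
    if (any(cfg$spike_days$multiplier <= 0)) {
      stop_config("spike_days", "has a non-positive multiplier")
    }
  }
  k <- length(cfg$scheme)
  if (length(cfg$category_prior) != k) {
    stop_config("category_prior", "length must match the category scheme")
  }
  if (any(cfg$category_prior < 0) || abs(sum(cfg$category_prior) - 1) > 1e-9) {
    stop_config("category_prior", "must be a probability vector summing to 1")
  }
  if (!identical(sort(names(cfg$signature_vocab)), sort(cfg$scheme))) {
    stop_config("signature_vocab", "must be named by the category scheme")
  }
  sig <- unlist(cfg$signature_vocab, use.names = FALSE)
  if (anyDuplicated(sig)) {
    stop_config("signature_vocab", "per-category signature lists must be disjoint")
  }
  for (field in c("hashtag_prob", "retweet_prob", "signature_rate", "rater_agreement")) {
    if (cfg[[field]] < 0 || cfg[[field]] > 1) stop_config(field, "must lie in [0, 1]")
  }
  if (length(cfg$url_prob_per_category) != k ||
      any(cfg$url_prob_per_category < 0 | cfg$url_prob_per_category > 1)) {
    stop_config("url_prob_per_category", "must be k probabilities in [0, 1]")
  }
  if (cfg$background_zipf_exponent <= 0) stop_config("background_zipf_exponent", "must be > 0")
  if (cfg$hashtag_zipf_exponent <= 0) stop_config("hashtag_zipf_exponent", "must be > 0")
  if (cfg$user_zipf_exponent <= 0) stop_config("user_zipf_exponent", "must be > 0")
  if (cfg$n_users < 1L) stop_config("n_users", "must be >= 1")
  if (length(cfg$tokens_per_tweet) != 2L ||
      cfg$tokens_per_tweet[1L] < 1L ||
      cfg$tokens_per_tweet[2L] < cfg$tokens_per_tweet[1L]) {
    stop_config("tokens_per_tweet", "must be (min, max) with 1 <= min <= max")
  }
  invisible(cfg)
}

#' Generate a synthetic tweet corpus with known category labels
#'
#' Each day's tweet count is Poisson with the configured base rate times the
#' day's spike multiplier. Each original tweet draws a category from the
#' prior and contains at least one signature stem of that category plus
#' Zipf-sampled background stems; retweets copy an earlier original verbatim
#' with an "RT @user: " prefix and carry the source's category. Output is
#' reproducible given the config (which includes the seed).
#'
#' @param config a [generator_config()].
#' @return list with `store` (a `tweet_store`), `truth` (tibble `tweet_id`,
#'   `category`: every tweet's generating category), and `day_counts` (the
#'   Poisson draw per day, summing to the corpus size).
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  cfg <- config
  mult <- rep(1, cfg$n_days)
  if (nrow(cfg$spike_days) > 0) mult[cfg$spike_days$day + 1L] <- cfg$spike_days$multiplier
  day_counts <- withr::with_seed(cfg$seed, rpois(cfg$n_days, cfg$base_rate * mult))
  n <- sum(day_counts)
  if (n == 0L) {
    return(list(store = new_tweet_store(),
                truth = tibble::tibble(tweet_id = character(0),
                                       category = character(0)),
                day_counts = day_counts))
  }
  withr::with_seed(cfg$seed + 1L, {
    bg_prob <- {
      p <- seq_along(cfg$background_vocab)^(-cfg$background_zipf_exponent)
      p / sum(p)
    }
    tag_prob <- {
      p <- seq_along(cfg$hashtag_vocab)^(-cfg$hashtag_zipf_exponent)
      p / sum(p)
    }
    day_of <- rep(seq_len(cfg$n_days) - 1L, day_counts)
    origin <- as.POSIXct("2014-06-01 00:00:00", tz = "UTC")
    created_at <- origin + day_of * 86400 + runif(n) * 86400

    ids <- sprintf("t%08d", seq_len(n))
    user_rank <- zipf_sample(n, cfg$n_users, cfg$user_zipf_exponent)
    users <- sprintf("user%05d", user_rank)
    k <- length(cfg$scheme)

    is_rt <- runif(n) < cfg$retweet_prob
    is_rt[1L] <- FALSE

    category <- character(n)
    text <- character(n)
    hashtags <- vector("list", n)
    has_url <- logical(n)
    retweet_of <- rep(NA_character_, n)
    originals <- integer(0)

    n_tok <- sample(seq(cfg$tokens_per_tweet[1L], cfg$tokens_per_tweet[2L]),
                    n, replace = TRUE)
    for (i in seq_len(n)) {
      if (is_rt[i] && length(originals) > 0L) {
        src <- originals[sample.int(length(originals), 1L)]
        category[i] <- category[src]
        text[i] <- paste0("RT @", users[src], ": ", text[src])
        hashtags[[i]] <- hashtags[[src]]
        has_url[i] <- has_url[src]
        retweet_of[i] <- ids[src]
      } else {
        ci <- sample.int(k, 1L, prob = cfg$category_prior)
        category[i] <- cfg$scheme[ci]
        sig_pool <- cfg$signature_vocab[[cfg$scheme[ci]]]
        toks <- character(n_tok[i])
        toks[1L] <- sig_pool[sample.int(length(sig_pool), 1L)]
        if (n_tok[i] > 1L) {
          for (j in 2L:n_tok[i]) {
            toks[j] <- if (runif(1L) < cfg$signature_rate) {
              sig_pool[sample.int(length(sig_pool), 1L)]
            } else {
              cfg$background_vocab[sample.int(length(bg_prob), 1L, prob = bg_prob)]
            }
          }
        }
        body <- paste(sample(toks), collapse = " ")
        hashtags[[i]] <- character(0)
        if (runif(1L) < cfg$hashtag_prob) {
          tag <- cfg$hashtag_vocab[sample.int(length(tag_prob), 1L, prob = tag_prob)]
          body <- paste0(body, " #", tag)
          hashtags[[i]] <- tag
        }
        if (runif(1L) < cfg$url_prob_per_category[ci]) {
          body <- paste0(body, " https://t.co/", ids[i])
          has_url[i] <- TRUE
        }
        text[i] <- body
        originals <- c(originals, i)
      }
    }

    store <- new_tweet_store(id = ids, text = text, created_at = created_at,
                             screen_name = users, hashtags = hashtags,
                             has_url = has_url, retweet_of = retweet_of)
    truth <- tibble::tibble(tweet_id = ids, category = category)
    list(store = store, truth = truth, day_counts = day_counts)
  })
}

#' Simulate independent raters over a true-label map
#'
#' Each rater reports the true category with probability `agreement`,
#' otherwise a uniformly random other category from the scheme.
#'
#' @param truth tibble with `tweet_id`, `category`.
#' @param n_raters number of raters (>= 2).
#' @param agreement probability in [0, 1].
#' @param seed integer seed.
#' @param scheme category scheme.
#' @return long-format rater table (`tweet_id`, `rater_id`, `category`).
#' @export
generate_rater_table <- function(truth, n_raters = 3L, agreement, seed,
                                 scheme = category_scheme()) {
  if (nrow(truth) == 0L) stop("true-label map is empty", call. = FALSE)
  if (n_raters < 2L) stop("n_raters must be >= 2", call. = FALSE)
  if (agreement < 0 || agreement > 1) stop("agreement must lie in [0, 1]", call. = FALSE)
  k <- length(scheme)
  true_idx <- match(truth$category, scheme)
  stopifnot(!anyNA(true_idx))
  n <- nrow(truth)
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_raters), function(r) {
      correct <- runif(n) < agreement
      reported <- true_idx
      wrong <- which(!correct)
      if (length(wrong) > 0L && k > 1L) {
        # uniform over the k-1 other categories
        shift <- sample.int(k - 1L, length(wrong), replace = TRUE)
        reported[wrong] <- ((true_idx[wrong] - 1L + shift) %% k) + 1L
      }
      tibble::tibble(tweet_id = truth$tweet_id,
                     rater_id = sprintf("rater%02d", r),
                     category = scheme[reported])
    })
    dplyr::bind_rows(out)
  })
}
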