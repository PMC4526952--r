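# In-memory reimplementation of the warehouse-style corpus queries: daily
# volume, Z-score spike detection, hashtag usage, user concentration,
# retweet structure, and per-day frequent stems.

#' Daily tweet counts
#'
#' Dense, zero-filled series over the store's UTC date span; the counts sum
#' to the store size.
#'
#' @param store a non-empty `tweet_store`.
#' @return tibble with `date` (Date, contiguous) and `count`.
#' @export
daily_counts <- function(store) {
  if (nrow(store) == 0L) stop("empty store has no date span", call. = FALSE)
  dates <- as.Date(store$created_at, tz = "UTC")
  span <- seq(min(dates), max(dates), by = "day")
  tab <- table(factor(as.character(dates), levels = as.character(span)))
  tibble::tibble(date = span, count = as.integer(tab))
}

#' Flag unusually high-volume days by Z score
#'
#' Z_i = (count_i - mean) / SD with the population SD (divisor n), computed
#' over the full series; a day is flagged when its Z score exceeds the
#' threshold. A constant series (SD = 0) flags nothing.
#'
#' @param series a daily-count tibble from [daily_counts()].
#' @param threshold Z-score cutoff (default 2.0).
#' @return list with `days` (tibble `date`, `count`, `z_score`, `flagged`),
#'   `flagged` (the flagged subset), `mean`, `sd`.
#' @export
zscore_spikes <- function(series, threshold = 2.0) {
  if (nrow(series) < 2L) stop("series must contain at least 2 days", call. = FALSE)
  m <- mean(series$count)
  s <- sqrt(mean((series$count - m)^2))
  z <- if (s == 0) rep(0, nrow(series)) else (series$count - m) / s
  days <- tibble::tibble(date = series$date, count = series$count,
                         z_score = z, flagged = s > 0 & z > threshold)
  list(days = days, flagged = days[days$flagged, ], mean = m, sd = s)
}

#' Hashtag usage statistics
#'
#' Counts every hashtag occurrence (a tag used twice in one tweet counts
#' twice). Relative frequency is count over total usages. Also reports how
#' many distinct tags were used fewer than `rare_cutoff` times.
#'
#' @param store a `tweet_store`.
#' @param rare_cutoff usage count below which a tag counts as rare
#'   (default 100).
#' @return list with `table` (tibble `tag`, `count`, `rel_freq`, sorted by
#'   count descending then tag), `n_distinct`, `total_usages`, `n_rare`.
#' @export
hashtag_stats <- function(store, rare_cutoff = 100L) {
  tags <- unlist(store$hashtags, use.names = FALSE)
  if (length(tags) == 0L) {
    return(list(table = tibble::tibble(tag = character(0), count = integer(0),
                                       rel_freq = numeric(0)),
                n_distinct = 0L, total_usages = 0L, n_rare = 0L))
  }
  tab <- table(tags)
  out <- tibble::tibble(tag = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$tag), ]
  out$rel_freq <- out$count / sum(out$count)
  list(table = out, n_distinct = nrow(out), total_usages = sum(out$count),
       n_rare = sum(out$count < rare_cutoff))
}

#' User-concentration summary
#'
#' Heavy users are those with at least `min_tweets` tweets; their pooled
#' share of the whole corpus quantifies how concentrated the conversation
#' is.
#'
#' @param store a `tweet_store`.
#' @param min_tweets heavy-user threshold (default 10).
#' @return list: `n_users`, `n_heavy_users`, `heavy_user_tweets`,
#'   `heavy_user_share` (fraction of all tweets), `per_user` tibble.
#' @export
user_concentration <- function(store, min_tweets = 10L) {
  if (nrow(store) == 0L) {
    return(list(n_users = 0L, n_heavy_users = 0L, heavy_user_tweets = 0L,
                heavy_user_share = 0,
                per_user = tibble::tibble(screen_name = character(0),
                                          count = integer(0))))
  }
  tab <- table(store$screen_name)
  per_user <- tibble::tibble(screen_name = names(tab), count = as.integer(tab))
  per_user <- per_user[order(-per_user$count, per_user$screen_name), ]
  heavy <- per_user$count >= min_tweets
  list(n_users = nrow(per_user),
       n_heavy_users = sum(heavy),
       heavy_user_tweets = sum(per_user$count[heavy]),
       heavy_user_share = sum(per_user$count[heavy]) / nrow(store),
       per_user = per_user)
}

#' Retweet summary
#'
#' Retweets are identified by [is_retweet()]. Per-message tallies key on the
#' source tweet id when known, else on the normalized text body after the
#' "RT @user:" prefix.
#'
#' @param store a `tweet_store`.
#' @param viral_cutoff tally above which a message counts as viral
#'   (default 500).
#' @return list: `total`, `n_retweets`, `fraction`, `tallies` tibble
#'   (`key`, `count`), `n_viral`.
#' @export
retweet_summary <- function(store, viral_cutoff = 500L) {
  rt <- is_retweet(store)
  n <- nrow(store)
  if (!any(rt)) {
    return(list(total = n, n_retweets = 0L, fraction = 0,
                tallies = tibble::tibble(key = character(0), count = integer(0)),
                n_viral = 0L))
  }
  key <- ifelse(!is.na(store$retweet_of[rt]), store$retweet_of[rt],
                tolower(trimws(sub("^RT @[^:]*:\\s*", "", store$text[rt]))))
  tab <- table(key)
  tallies <- tibble::tibble(key = names(tab), count = as.integer(tab))
  tallies <- tallies[order(-tallies$count, tallies$key), ]
  list(total = n, n_retweets = sum(rt), fraction = sum(rt) / n,
       tallies = tallies, n_viral = sum(tallies$count > viral_cutoff))
}

#' Most frequent stems on a given day
#'
#' Tokenizes and stems the texts of the tweets posted on `date` (UTC),
#' stopword-filtered, and returns the top `k` stems by count, ties broken by
#' stem ascending.
#'
#' @param store a `tweet_store`.
#' @param date a `Date` within the store's span.
#' @param k number of stems to return.
#' @return tibble `stem`, `count` (at most `k` rows).
#' @export
top_stems_for_day <- function(store, date, k = 10L) {
  date <- as.Date(date)
  span <- range(as.Date(store$created_at, tz = "UTC"))
  if (date < span[1L] || date > span[2L]) {
    stop(sprintf("date %s outside the store's span [%s, %s]",
                 date, span[1L], span[2L]), call. = FALSE)
  }
  sel <- as.Date(store$created_at, tz = "UTC") == date
  counts <- count_stems(text_to_stems(store$text[sel]))
  head(counts, k)
}
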