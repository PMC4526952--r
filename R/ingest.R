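# Reading, writing and filtering tweet archives.
#
# The JSON Lines dialect is a subset of Twitter API v1.1 fields:
#   {"id": str, "text": str, "created_at": ISO-8601 str,
#    "user": {"screen_name": str},
#    "entities": {"hashtags": [{"text": str}], "urls": [{"url": str}]},
#    "retweeted_status": {"id": str}}   (optional)
# A tweet store is a tibble with columns id, text, created_at (POSIXct UTC),
# screen_name, hashtags (list of character), has_url, retweet_of, ordered by
# (created_at, id), with a `skipped` attribute counting malformed lines.

#' Default topic keyword list
#'
#' A representative subset of the antibiotic collection keywords: generic
#' terms, a common abbreviation, specific drug names, and a common
#' misspelling. Terms match at token boundaries with a prefix rule, so
#' "antibiotic" also matches "antibiotics".
#'
#' @return lowercase character vector.
#' @export
default_include_terms <- function() {
  c("antibiotic", "antibiotics", "abx", "amoxicillin", "penicillin",
    "doxycycline", "cephalexin", "antiboitic")
}

new_tweet_store <- function(id = character(0), text = character(0),
                            created_at = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
                            screen_name = character(0), hashtags = list(),
                            has_url = logical(0), retweet_of = character(0),
                            skipped = 0L) {
  store <- tibble::tibble(
    id = as.character(id), text = as.character(text), created_at = created_at,
    screen_name = as.character(screen_name), hashtags = hashtags,
    has_url = as.logical(has_url),
    retweet_of = as.character(retweet_of)
  )
  store <- store[order(store$created_at, store$id), ]
  if (anyDuplicated(store$id)) stop("duplicate tweet ids in store", call. = FALSE)
  attr(store, "skipped") <- skipped
  class(store) <- c("tweet_store", class(store))
  store
}

parse_created_at <- function(x) {
  # ISO-8601 with offset or 'Z'; resolved to UTC
  ts <- as.POSIXct(sub("Z$", "+0000", x), format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (is.na(ts)) ts <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ts
}

parse_tweet_line <- function(line) {
  obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (is.null(obj$id) || is.null(obj$text) || is.null(obj$created_at)) {
    stop("missing required field")
  }
  ts <- parse_created_at(obj$created_at)
  if (is.na(ts)) stop("unparseable created_at")
  tags <- vapply(obj$entities$hashtags %||% list(),
                 function(h) as.character(h$text), character(1L))
  if (any(grepl("\\s|^#", tags))) stop("malformed hashtag entity")
  urls <- obj$entities$urls %||% list()
  list(
    id = as.character(obj$id), text = as.character(obj$text), created_at = ts,
    screen_name = as.character(obj$user$screen_name %||% ""),
    hashtags = tolower(tags),
    has_url = length(urls) > 0L || grepl("https?://", obj$text),
    retweet_of = as.character(obj$retweeted_status$id %||% NA_character_)
  )
}

#' Read a JSON Lines tweet archive
#'
#' One JSON object per line. Malformed lines are skipped and counted; the
#' count is available as `attr(store, "skipped")`. A file with no valid
#' lines yields an empty store with a warning.
#'
#' @param path file path.
#' @return a `tweet_store` tibble ordered by (`created_at`, `id`).
#' @export
read_tweets_jsonl <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parsed <- list()
  skipped <- 0L
  for (line in lines) {
    rec <- tryCatch(parse_tweet_line(line), error = function(e) NULL)
    if (is.null(rec)) skipped <- skipped + 1L else parsed[[length(parsed) + 1L]] <- rec
  }
  if (length(parsed) == 0L) {
    if (length(lines) > 0L) warning("no valid tweet lines in file")
    return(new_tweet_store(skipped = skipped))
  }
  new_tweet_store(
    id = vapply(parsed, `[[`, character(1L), "id"),
    text = vapply(parsed, `[[`, character(1L), "text"),
    created_at = as.POSIXct(vapply(parsed, function(p) as.numeric(p$created_at), numeric(1L)),
                            origin = "1970-01-01", tz = "UTC"),
    screen_name = vapply(parsed, `[[`, character(1L), "screen_name"),
    hashtags = lapply(parsed, `[[`, "hashtags"),
    has_url = vapply(parsed, `[[`, logical(1L), "has_url"),
    retweet_of = vapply(parsed, `[[`, character(1L), "retweet_of"),
    skipped = skipped
  )
}

#' Write a tweet store as JSON Lines
#'
#' Inverse of [read_tweets_jsonl()]: one JSON object per tweet with stable
#' field order, so that write-then-read is lossless.
#'
#' @param store a `tweet_store`.
#' @param path destination path.
#' @export
write_tweets_jsonl <- function(store, path) {
  lines <- vapply(seq_len(nrow(store)), function(i) {
    obj <- list(
      id = store$id[i],
      text = store$text[i],
      created_at = format(store$created_at[i], "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC"),
      user = list(screen_name = store$screen_name[i]),
      entities = list(
        hashtags = lapply(store$hashtags[[i]], function(t) list(text = t)),
        urls = if (isTRUE(store$has_url[i])) list(list(url = "https://t.co/x")) else list()
      )
    )
    if (!is.na(store$retweet_of[i])) {
      obj$retweeted_status <- list(id = store$retweet_of[i])
    }
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

term_matches_tokens <- function(tokens, terms) {
  for (term in terms) {
    if (any(startsWith(tokens, term))) return(TRUE)
  }
  FALSE
}

#' Keyword-filter a tweet store
#'
#' Retains a tweet iff at least one `include_term` matches the lowercased
#' text at a token boundary (a term matches a token or a token prefix, so
#' "antibiotic" covers "antibiotics"), and no `exclude_pattern` occurs as a
#' plain substring of the lowercased text (so the cashtag "$abx" can reject
#' stock chatter that the token rule cannot see). Order is preserved and the
#' operation is idempotent.
#'
#' @param store a `tweet_store`.
#' @param include_terms non-empty lowercase keyword vector.
#' @param exclude_patterns lowercase substrings whose presence rejects a
#'   tweet (default none).
#' @return filtered `tweet_store` (a subsequence of the input).
#' @export
filter_tweets <- function(store, include_terms, exclude_patterns = character(0)) {
  if (length(include_terms) == 0L) {
    stop("include_terms must be non-empty for a filtering run", call. = FALSE)
  }
  if (any(include_terms != tolower(include_terms))) {
    stop("include_terms must be lowercase", call. = FALSE)
  }
  low <- tolower(store$text)
  token_lists <- strsplit(low, "[^a-z0-9]+")
  keep <- vapply(token_lists, term_matches_tokens, logical(1L), terms = include_terms)
  for (pat in tolower(exclude_patterns)) {
    keep <- keep & !grepl(pat, low, fixed = TRUE)
  }
  out <- store[keep, ]
  attr(out, "skipped") <- attr(store, "skipped")
  out
}

#' Identify retweets in a store
#'
#' A tweet is a retweet if its `retweet_of` field is set, or failing that if
#' its text begins with the conventional "RT @" prefix.
#'
#' @param store a `tweet_store`.
#' @return logical vector.
#' @export
is_retweet <- function(store) {
  !is.na(store$retweet_of) | startsWith(store$text, "RT @")
}
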