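# Corpus-wide application of a trained model: argmax category assignment,
# category frequency estimates, and threshold-based retrieval of confident
# tweets for one category.

#' Assign each tweet to its highest-scoring category
#'
#' Exact score ties break by scheme order (the first category wins).
#'
#' @param scores score matrix with one column per category, in scheme order.
#' @param scheme category scheme.
#' @return character vector of category names (empty for an empty matrix).
#' @export
assign_categories <- function(scores, scheme = category_scheme()) {
  if (ncol(scores) != length(scheme)) {
    stop("score columns must match the category scheme", call. = FALSE)
  }
  if (nrow(scores) == 0L) return(character(0))
  scheme[max.col(scores, ties.method = "first")]
}

#' Category frequency estimates from assignments
#'
#' @param assignments category name per tweet.
#' @param scheme category scheme.
#' @return tibble `category`, `count`, `fraction` (fractions sum to 1;
#'   empty input yields an empty table).
#' @export
category_frequencies <- function(assignments, scheme = category_scheme()) {
  if (length(assignments) == 0L) {
    return(tibble::tibble(category = character(0), count = integer(0),
                          fraction = numeric(0)))
  }
  counts <- table(factor(assignments, levels = scheme))
  tibble::tibble(category = scheme, count = as.integer(counts),
                 fraction = as.integer(counts) / length(assignments))
}

#' Retrieve confident tweets for one category
#'
#' Returns the tweets whose score for `category` is at least `threshold`
#' (closed lower bound), sorted by that score descending with ties broken by
#' tweet id ascending.
#'
#' @param scores score matrix with rownames = tweet ids and scheme-ordered,
#'   named columns.
#' @param category a category name in the scheme.
#' @param threshold score cutoff in [0, 1].
#' @param scheme category scheme.
#' @return tibble `tweet_id`, `score`.
#' @export
retrieve_tweets <- function(scores, category, threshold,
                            scheme = category_scheme()) {
  if (!category %in% scheme) {
    stop(sprintf("unknown category '%s'", category), call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  s <- scores[, match(category, scheme)]
  ids <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  keep <- which(s >= threshold)
  out <- tibble::tibble(tweet_id = ids[keep], score = unname(s[keep]))
  out[order(-out$score, out$tweet_id), ]
}
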