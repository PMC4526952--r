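# Multi-rater label adjudication and chance-corrected agreement.

#' The default tweet category scheme
#'
#' Nine topic categories used for antibiotic-related tweets. The order is
#' fixed and defines output-unit order in the classifier and tie-breaking in
#' category assignment.
#'
#' @return ordered character vector of category names.
#' @export
category_scheme <- function() {
  c("Advertisement", "Advice/Information", "Animals", "General use",
    "Other", "Resistance", "Side effects", "Wanting/Needing", "Misuse")
}

# votes: long tibble (tweet_id, rater_id, category); checks completeness
validate_rater_table <- function(votes, scheme = category_scheme()) {
  stopifnot(all(c("tweet_id", "rater_id", "category") %in% names(votes)))
  if (nrow(votes) == 0L) stop("rater table is empty", call. = FALSE)
  bad <- setdiff(unique(votes$category), scheme)
  if (length(bad)) {
    stop(sprintf("categories outside the scheme: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  per_item <- table(votes$tweet_id)
  if (length(unique(as.integer(per_item))) != 1L) {
    stop("incomplete rater table: items have differing numbers of votes",
         call. = FALSE)
  }
  if (anyDuplicated(votes[, c("tweet_id", "rater_id")])) {
    stop("duplicate (tweet_id, rater_id) votes", call. = FALSE)
  }
  invisible(as.integer(per_item[1L]))
}

#' Adjudicate rater votes into a labeled set
#'
#' An item receives the category that gathered at least `min_agree` votes;
#' items where no category reaches that many votes are dropped (with three
#' raters and `min_agree = 2` the winner is unique whenever it exists).
#'
#' @param votes long-format rater table: columns `tweet_id`, `rater_id`,
#'   `category`.
#' @param min_agree minimum votes a category needs (default 2).
#' @param scheme category scheme.
#' @return list with `labels` (tibble `tweet_id`, `category`), `dropped`
#'   (character ids), and `votes` provenance.
#' @export
adjudicate <- function(votes, min_agree = 2L, scheme = category_scheme()) {
  n_raters <- validate_rater_table(votes, scheme)
  if (min_agree < 2L) stop("min_agree must be at least 2", call. = FALSE)
  if (min_agree > n_raters) {
    stop(sprintf("min_agree (%d) exceeds the number of raters (%d)",
                 min_agree, n_raters), call. = FALSE)
  }
  split_votes <- split(votes$category, votes$tweet_id)
  winner <- vapply(split_votes, function(v) {
    tab <- table(v)
    o <- order(-as.integer(tab), names(tab))  # count desc, category name asc
    if (tab[o[1L]] >= min_agree) names(tab)[o[1L]] else NA_character_
  }, character(1L))
  labels <- tibble::tibble(tweet_id = names(winner), category = unname(winner))
  dropped <- labels$tweet_id[is.na(labels$category)]
  labels <- labels[!is.na(labels$category), ]
  list(labels = labels, dropped = dropped, votes = votes)
}

#' Fleiss' kappa for a complete rater table
#'
#' Chance-corrected agreement for a fixed number of raters over many items:
#' \deqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)} with per-item
#' agreement \eqn{P_i = (\sum_j n_{ij}^2 - n) / (n(n-1))}, marginal category
#' shares \eqn{p_j = \sum_i n_{ij} / (N n)}, and \eqn{\bar P_e = \sum_j
#' p_j^2}. If every vote lands in one category (\eqn{\bar P_e = 1}) the
#' statistic is returned as 1 with a warning, reflecting perfect agreement.
#'
#' @inheritParams adjudicate
#' @return kappa in [-1, 1].
#' @export
fleiss_kappa <- function(votes, scheme = category_scheme()) {
  n_raters <- validate_rater_table(votes, scheme)
  if (n_raters < 2L) stop("Fleiss' kappa needs at least 2 raters", call. = FALSE)
  items <- unique(votes$tweet_id)
  if (length(items) < 2L) stop("Fleiss' kappa needs at least 2 items", call. = FALSE)
  counts <- table(factor(votes$tweet_id, levels = items),
                  factor(votes$category, levels = scheme))
  counts <- matrix(as.integer(counts), nrow = length(items))
  n <- n_raters
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_j <- colSums(counts) / (length(items) * n)
  P_bar <- mean(P_i)
  Pe_bar <- sum(p_j^2)
  if (abs(1 - Pe_bar) < .Machine$double.eps^0.5) {
    warning("all votes fall in a single category; kappa reported as 1")
    return(1)
  }
  (P_bar - Pe_bar) / (1 - Pe_bar)
}

#' Read / write long-format rater votes as CSV
#'
#' Columns: `tweet_id`, `rater_id`, `category`.
#' @param path CSV file path.
#' @param votes long-format rater table.
#' @export
read_votes_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  tibble::as_tibble(df[, c("tweet_id", "rater_id", "category")])
}

#' @rdname read_votes_csv
#' @export
write_votes_csv <- function(votes, path) {
  utils::write.csv(votes, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
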