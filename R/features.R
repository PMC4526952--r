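# Bag-of-stems feature engineering: tweets are encoded as fixed-length binary
# vectors consisting of stem-presence bits (class-informed vocabulary), ten
# tweet-length bins of 10 characters each, and one URL flag.

# Snowball English stopword list
STOPWORDS_EN <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you", "your",
  "yours", "yourself", "yourselves", "he", "him", "his", "himself", "she",
  "her", "hers", "herself", "it", "its", "itself", "they", "them", "their",
  "theirs", "themselves", "what", "which", "who", "whom", "this", "that",
  "these", "those", "am", "is", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing", "would",
  "should", "could", "ought", "a", "an", "the", "and", "but", "if", "or",
  "because", "as", "until", "while", "of", "at", "by", "for", "with", "about",
  "against", "between", "into", "through", "during", "before", "after",
  "above", "below", "to", "from", "up", "down", "in", "out", "on", "off",
  "over", "under", "again", "further", "then", "once", "here", "there",
  "when", "where", "why", "how", "all", "any", "both", "each", "few", "more",
  "most", "other", "some", "such", "no", "nor", "not", "only", "own", "same",
  "so", "than", "too", "very", "s", "t", "can", "will", "just", "don",
  "cant", "wont", "im", "ive", "id", "youre", "hes", "shes", "its", "were",
  "theyre", "isnt", "arent", "wasnt", "werent", "dont", "doesnt", "didnt",
  "rt"
)

#' Tokenize tweet text
#'
#' Lowercases, strips URLs and \code{@}-mentions, removes the leading
#' \code{#} of hashtags (keeping the tag text), splits on non-alphanumeric
#' characters, and drops empty tokens and English stopwords.
#'
#' @param text character vector of raw tweet texts.
#' @param remove_stopwords drop common English function words (default TRUE).
#' @return a list of character token vectors, one per input text.
#' @export
#' @examples
#' tokenize_text("RT @USERID: 80% of all antibiotics")
tokenize_text <- function(text, remove_stopwords = TRUE) {
  cleaned <- tolower(text)
  cleaned <- gsub("https?://\\S+", " ", cleaned)
  cleaned <- gsub("@\\w+", " ", cleaned)
  cleaned <- gsub("#", " ", cleaned, fixed = TRUE)
  toks <- strsplit(cleaned, "[^a-z0-9]+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (remove_stopwords) tk <- tk[!tk %in% STOPWORDS_EN]
    tk
  })
}

# tokenize + stem a character vector of texts -> list of stem vectors;
# stems are computed once per distinct token
text_to_stems <- function(text, remove_stopwords = TRUE) {
  toks <- tokenize_text(text, remove_stopwords)
  lens <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat) == 0L) return(toks)
  uniq <- unique(flat)
  stemmed <- stem_tokens(uniq)
  flat_stemmed <- stemmed[match(flat, uniq)]
  split_idx <- rep.int(seq_along(toks), lens)
  out <- rep(list(character(0)), length(toks))
  filled <- split(flat_stemmed, split_idx)
  out[as.integer(names(filled))] <- filled
  unname(out)
}

count_stems <- function(stem_lists) {
  all_stems <- unlist(stem_lists, use.names = FALSE)
  if (length(all_stems) == 0L) {
    return(tibble::tibble(stem = character(0), count = integer(0)))
  }
  tab <- table(all_stems)
  out <- tibble::tibble(stem = names(tab), count = as.integer(tab))
  # frequency descending, stem ascending on ties
  out[order(-out$count, out$stem), ]
}

top_stems <- function(stem_lists, k) {
  counts <- count_stems(stem_lists)
  head(counts$stem, k)
}

#' Build the class-informed bag-of-stems vocabulary
#'
#' Takes, for every category, the most frequent stems among that category's
#' labeled tweets (up to `per_class_top`), plus the most frequent stems over
#' the whole corpus (up to `overall_top`), and returns their deduplicated
#' union in deterministic order: per-class lists in scheme order first, then
#' the overall list. Frequency ties break by stem (ascending).
#'
#' @param labeled_texts character vector of labeled tweet texts.
#' @param labels category name per labeled text.
#' @param all_texts character vector of corpus texts used for the overall
#'   frequency list (typically much larger than the labeled set).
#' @param scheme category scheme from [category_scheme()].
#' @param per_class_top maximum stems contributed per category (default 50).
#' @param overall_top maximum stems contributed by the overall list
#'   (default 1000).
#' @return an object of class `tweet_vocabulary`: list with `stems` (ordered
#'   character vector) and a `construction` record.
#' @export
build_vocabulary <- function(labeled_texts, labels, all_texts,
                             scheme = category_scheme(),
                             per_class_top = 50L, overall_top = 1000L) {
  stopifnot(length(labeled_texts) == length(labels))
  if (length(labeled_texts) == 0L) stop("labeled set is empty", call. = FALSE)
  labeled_stems <- text_to_stems(labeled_texts)
  per_class <- lapply(scheme, function(cls) {
    idx <- which(labels == cls)
    if (length(idx) == 0L) {
      warning(sprintf("class '%s' has no labeled tweets; contributes no stems", cls))
      return(character(0))
    }
    top_stems(labeled_stems[idx], per_class_top)
  })
  names(per_class) <- scheme
  overall <- top_stems(text_to_stems(all_texts), overall_top)
  stems <- unique(c(unlist(per_class, use.names = FALSE), overall))
  structure(
    list(stems = stems,
         construction = list(per_class = per_class, overall = overall,
                             per_class_top = per_class_top,
                             overall_top = overall_top)),
    class = "tweet_vocabulary"
  )
}

#' Define the frozen feature layout
#'
#' The feature vector is `|vocabulary|` stem-presence bits, then 10 binary
#' tweet-length bins (0-9, 10-19, ..., 90+ characters; lengths of 100 or more
#' clamp into the top bin), then one URL flag. With a 1372-stem vocabulary the
#' total dimension is 1383.
#'
#' @param vocabulary a `tweet_vocabulary` or plain character vector of stems.
#' @return an object of class `feature_spec` with fields `stems`,
#'   `n_length_bins`, `bin_width`, `total_dim`.
#' @export
feature_spec <- function(vocabulary) {
  stems <- if (inherits(vocabulary, "tweet_vocabulary")) vocabulary$stems else vocabulary
  stopifnot(is.character(stems), !anyDuplicated(stems))
  structure(
    list(stems = stems, n_length_bins = 10L, bin_width = 10L,
         total_dim = length(stems) + 10L + 1L),
    class = "feature_spec"
  )
}

length_bin_index <- function(text_len, spec) {
  pmin(text_len %/% spec$bin_width, spec$n_length_bins - 1L) + 1L
}

#' Encode tweets as binary feature vectors
#'
#' @param store a tweet store (see [read_tweets_jsonl()]) or a data frame
#'   with columns `text` and `has_url`.
#' @param spec a frozen [feature_spec()].
#' @return binary matrix, one row per tweet (rownames = tweet ids when
#'   available), `spec$total_dim` columns; exactly one length-bin bit is set
#'   per row.
#' @export
featurize_tweets <- function(store, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  n <- nrow(store)
  X <- matrix(0, nrow = n, ncol = spec$total_dim)
  if (n == 0L) return(X)
  stem_lists <- text_to_stems(store$text)
  nv <- length(spec$stems)
  for (i in seq_len(n)) {
    idx <- match(unique(stem_lists[[i]]), spec$stems)
    idx <- idx[!is.na(idx)]
    if (length(idx)) X[i, idx] <- 1
  }
  bins <- length_bin_index(nchar(store$text, type = "chars"), spec)
  X[cbind(seq_len(n), nv + bins)] <- 1
  X[, nv + spec$n_length_bins + 1L] <- as.numeric(store$has_url)
  if (!is.null(store$id)) rownames(X) <- store$id
  X
}

#' Serialize / restore a feature spec as JSON
#'
#' @param spec a [feature_spec()].
#' @param path file path.
#' @return `read_feature_spec` returns the restored `feature_spec`.
#' @export
write_feature_spec <- function(spec, path) {
  stopifnot(inherits(spec, "feature_spec"))
  jsonlite::write_json(
    list(format = "tweetdbn-feature-spec-1", stems = spec$stems,
         n_length_bins = spec$n_length_bins, bin_width = spec$bin_width),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_spec
#' @export
read_feature_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tweetdbn-feature-spec-1")) {
    stop("unrecognized feature spec file format", call. = FALSE)
  }
  feature_spec(as.character(obj$stems))
}
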