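# English Snowball ("Porter2") stemming algorithm, implemented from the
# published algorithm definition. Operates on single lowercase words; the
# vectorized entry point is stem_tokens().
#
# Conventions: vowels are a,e,i,o,u,y; a leading y, or a y after a vowel, is
# marked Y (consonant) during stemming and restored at the end. R1 is the
# region after the first non-vowel that follows a vowel (with special cases
# for gener-/commun-/arsen-); R2 is the same definition applied within R1.

P2_VOWELS <- c("a", "e", "i", "o", "u", "y")
P2_DOUBLES <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
P2_LI_ENDING <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

p2_exceptions1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

p2_exceptions2 <- c("inning", "outing", "canning", "herring", "earring",
                    "proceed", "exceed", "succeed")

p2_is_vowel <- function(ch) ch %in% P2_VOWELS  # Y (marked) is a consonant

p2_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1L]]

# 1-based start index of R1 / R2; length(word)+1 when the region is empty
p2_r1_start <- function(w) {
  for (pre in c("gener", "commun", "arsen")) {
    if (startsWith(w, pre)) return(nchar(pre) + 1L)
  }
  ch <- p2_chars(w)
  n <- length(ch)
  if (n < 2L) return(n + 1L)
  for (i in seq_len(n - 1L)) {
    if (p2_is_vowel(ch[i]) && !p2_is_vowel(ch[i + 1L])) return(i + 2L)
  }
  n + 1L
}

p2_region_start_from <- function(w, from) {
  ch <- p2_chars(w)
  n <- length(ch)
  if (from > n) return(n + 1L)
  i <- from
  while (i < n) {
    if (p2_is_vowel(ch[i]) && !p2_is_vowel(ch[i + 1L])) return(i + 2L)
    i <- i + 1L
  }
  n + 1L
}

# suffix (known to match) lies in the region starting at `rstart`
p2_in_region <- function(w, suffix, rstart) {
  nchar(w) - nchar(suffix) + 1L >= rstart
}

p2_ends_short_syllable <- function(w) {
  ch <- p2_chars(w)
  n <- length(ch)
  if (n == 2L) {
    return(p2_is_vowel(ch[1L]) && !p2_is_vowel(ch[2L]))
  }
  if (n >= 3L) {
    c2 <- ch[n]
    v <- ch[n - 1L]
    c1 <- ch[n - 2L]
    return(!p2_is_vowel(c1) && p2_is_vowel(v) &&
             !p2_is_vowel(c2) && !(c2 %in% c("w", "x", "Y")))
  }
  FALSE
}

p2_is_short_word <- function(w, r1) {
  p2_ends_short_syllable(w) && r1 > nchar(w)
}

p2_has_vowel <- function(part) {
  any(p2_is_vowel(p2_chars(part)))
}

p2_longest_suffix <- function(w, suffixes) {
  hits <- suffixes[vapply(suffixes, function(s) endsWith(w, s), logical(1L))]
  if (length(hits) == 0L) return(NA_character_)
  hits[which.max(nchar(hits))]
}

p2_drop <- function(w, k) substr(w, 1L, nchar(w) - k)

porter2_stem_word <- function(word) {
  w <- word
  if (nchar(w) <= 2L) return(w)
  w <- sub("^'", "", w)
  if (w %in% names(p2_exceptions1)) return(unname(p2_exceptions1[w]))
  if (nchar(w) <= 2L) return(w)

  # mark consonant y
  ch <- p2_chars(w)
  if (ch[1L] == "y") ch[1L] <- "Y"
  if (length(ch) >= 2L) {
    for (i in 2L:length(ch)) {
      if (ch[i] == "y" && p2_is_vowel(ch[i - 1L])) ch[i] <- "Y"
    }
  }
  w <- paste(ch, collapse = "")

  r1 <- p2_r1_start(w)
  r2 <- p2_region_start_from(w, r1)

  # Step 0: apostrophe suffixes
  s0 <- p2_longest_suffix(w, c("'s'", "'s", "'"))
  if (!is.na(s0)) w <- p2_drop(w, nchar(s0))

  # Step 1a
  s1a <- p2_longest_suffix(w, c("sses", "ied", "ies", "us", "ss", "s"))
  if (!is.na(s1a)) {
    if (s1a == "sses") {
      w <- paste0(p2_drop(w, 4L), "ss")
    } else if (s1a %in% c("ied", "ies")) {
      w <- if (nchar(w) - 3L > 1L) paste0(p2_drop(w, 3L), "i") else paste0(p2_drop(w, 3L), "ie")
    } else if (s1a == "s") {
      # delete if a vowel precedes the letter immediately before the s
      stem_part <- p2_drop(w, 1L)
      if (nchar(stem_part) >= 2L && p2_has_vowel(substr(stem_part, 1L, nchar(stem_part) - 1L))) {
        w <- stem_part
      }
    }
    # "us", "ss": leave unchanged
  }

  if (w %in% p2_exceptions2) return(gsub("Y", "y", w))

  # Step 1b
  s1b <- p2_longest_suffix(w, c("eedly", "ingly", "edly", "eed", "ing", "ed"))
  if (!is.na(s1b)) {
    if (s1b %in% c("eed", "eedly")) {
      if (p2_in_region(w, s1b, r1)) w <- paste0(p2_drop(w, nchar(s1b)), "ee")
    } else {
      stem_part <- p2_drop(w, nchar(s1b))
      if (p2_has_vowel(stem_part)) {
        w <- stem_part
        tail2 <- if (nchar(w) >= 2L) substr(w, nchar(w) - 1L, nchar(w)) else ""
        if (tail2 %in% c("at", "bl", "iz")) {
          w <- paste0(w, "e")
        } else if (tail2 %in% P2_DOUBLES) {
          w <- p2_drop(w, 1L)
        } else if (p2_is_short_word(w, r1)) {
          w <- paste0(w, "e")
        }
      }
    }
  }

  # Step 1c: y/Y -> i when preceded by a non-vowel that is not word-initial
  n <- nchar(w)
  if (n >= 3L && substr(w, n, n) %in% c("y", "Y")) {
    prev <- substr(w, n - 1L, n - 1L)
    if (!p2_is_vowel(prev)) w <- paste0(p2_drop(w, 1L), "i")
  }

  # Step 2 (in R1)
  step2 <- list(
    ization = "ize",ational = "ate", fulness = "ful", ousness = "ous",
    iveness = "ive", tional = "tion", biliti = "ble", lessli = "less",
    entli = "ent", ation = "ate", alism = "al", aliti = "al", ousli = "ous",
    iviti = "ive", fulli = "ful", enci = "ence", anci = "ance", abli = "able",
    izer = "ize", ator = "ate", alli = "al", bli = "ble", ogi = "og",
    li = ""
  )
  s2 <- p2_longest_suffix(w, names(step2))
  if (!is.na(s2) && p2_in_region(w, s2, r1)) {
    if (s2 == "ogi") {
      if (substr(w, nchar(w) - 3L, nchar(w) - 3L) == "l") {
        w <- paste0(p2_drop(w, 3L), "og")
      }
    } else if (s2 == "li") {
      if (substr(w, nchar(w) - 2L, nchar(w) - 2L) %in% P2_LI_ENDING) {
        w <- p2_drop(w, 2L)
      }
    } else {
      w <- paste0(p2_drop(w, nchar(s2)), step2[[s2]])
    }
  }

  # Step 3 (in R1; "ative" only in R2)
  step3 <- list(ational = "ate", tional = "tion", alize = "al", icate = "ic",
                iciti = "ic", ative = "", ical = "ic", ness = "", ful = "")
  s3 <- p2_longest_suffix(w, names(step3))
  if (!is.na(s3) && p2_in_region(w, s3, r1)) {
    if (s3 == "ative") {
      if (p2_in_region(w, s3, r2)) w <- p2_drop(w, 5L)
    } else {
      w <- paste0(p2_drop(w, nchar(s3)), step3[[s3]])
    }
  }

  # Step 4 (in R2)
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic")
  s4 <- p2_longest_suffix(w, step4)
  if (!is.na(s4) && p2_in_region(w, s4, r2)) {
    if (s4 == "ion") {
      prev <- substr(w, nchar(w) - 3L, nchar(w) - 3L)
      if (prev %in% c("s", "t")) w <- p2_drop(w, 3L)
    } else {
      w <- p2_drop(w, nchar(s4))
    }
  }

  # Step 5
  n <- nchar(w)
  if (n >= 1L && substr(w, n, n) == "e") {
    if (p2_in_region(w, "e", r2)) {
      w <- p2_drop(w, 1L)
    } else if (p2_in_region(w, "e", r1) && !p2_ends_short_syllable(p2_drop(w, 1L))) {
      w <- p2_drop(w, 1L)
    }
  } else if (n >= 2L && substr(w, n, n) == "l") {
    if (p2_in_region(w, "l", r2) && substr(w, n - 1L, n - 1L) == "l") {
      w <- p2_drop(w, 1L)
    }
  }

  gsub("Y", "y", w)
}

#' Stem lowercase tokens with the English Snowball (Porter2) algorithm
#'
#' Reduces each token to its stem, e.g. \code{"antibiotics"} to
#' \code{"antibiot"} and \code{"resistance"} to \code{"resist"}. Tokens are
#' expected lowercase (as produced by [tokenize_text()]); purely numeric
#' tokens are returned unchanged.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems, same length as `tokens`.
#' @export
#' @examples
#' stem_tokens(c("antibiotics", "resistance", "running"))
stem_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  vapply(tokens, porter2_stem_word, character(1L), USE.NAMES = FALSE)
}
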