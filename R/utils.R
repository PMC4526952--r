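#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif rnorm sd
#' @importFrom utils head write.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib tweetdbn, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax with max-shift for numerical stability
softmax_rows <- function(m) {
  shifted <- m - apply(m, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

# Draw n ranks in 1..k with P(rank r) proportional to r^(-s).
# Exact normalization over the finite support.
zipf_sample <- function(n, k, s) {
  stopifnot(k >= 1L, s > 0)
  p <- (seq_len(k))^(-s)
  sample.int(k, size = n, replace = TRUE, prob = p / sum(p))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
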