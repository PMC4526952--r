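# Bernoulli restricted Boltzmann machine with contrastive-divergence
# training. The RBM over visible v and hidden h has energy
#   E(v, h) = -b'v - c'h - v'Wh
# so p(h_j = 1 | v) = sigmoid(c_j + sum_i v_i W_ij) and symmetrically for
# the visible units. CD-k approximates the log-likelihood gradient with k
# alternating Gibbs steps from the data.

#' Create an RBM with random weights
#'
#' Weights are zero-mean Gaussian with standard deviation `init_sd`; both
#' bias vectors start at zero. Draws from the current RNG stream.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param init_sd weight initialization SD (default 0.01).
#' @return an `rbm` object: list with `W` (visible x hidden), `b` (visible
#'   bias), `c` (hidden bias).
#' @export
rbm_init <- function(n_visible, n_hidden, init_sd = 0.01) {
  structure(
    list(W = matrix(rnorm(n_visible * n_hidden, sd = init_sd), n_visible, n_hidden),
         b = numeric(n_visible), c = numeric(n_hidden)),
    class = "rbm"
  )
}

#' Hidden-unit activation probabilities
#'
#' p(h_j = 1 | v) = sigmoid(c_j + sum_i v_i W_ij), computed row-wise for a
#' matrix of visible configurations.
#'
#' @param rbm an `rbm`.
#' @param v numeric matrix (rows = configurations) or vector matching the
#'   visible dimension.
#' @return matrix of probabilities (rows x n_hidden).
#' @export
rbm_hidden_probs <- function(rbm, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(v) != nrow(rbm$W)) stop("visible dimension mismatch", call. = FALSE)
  sigmoid(sweep(v %*% rbm$W, 2L, rbm$c, `+`))
}

#' Visible-unit activation probabilities
#'
#' @param rbm an `rbm`.
#' @param h numeric matrix (rows = configurations) or vector matching the
#'   hidden dimension.
#' @return matrix of probabilities (rows x n_visible).
#' @export
rbm_visible_probs <- function(rbm, h) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  if (ncol(h) != ncol(rbm$W)) stop("hidden dimension mismatch", call. = FALSE)
  sigmoid(sweep(tcrossprod(h, rbm$W), 2L, rbm$b, `+`))
}

#' One contrastive-divergence parameter update
#'
#' Positive phase from the data batch; negative phase from `k` alternating
#' Gibbs steps in which hidden states are sampled, while the final visible
#' and hidden phases use probabilities (mean-field). The step is
#' `learning_rate * (positive - negative associations) / batch_size`.
#'
#' @param rbm an `rbm`.
#' @param batch binary matrix (rows = examples).
#' @param learning_rate step size.
#' @param k number of Gibbs steps (CD-k, default 1).
#' @return updated `rbm`, with attribute `recon_error` (mean squared
#'   reconstruction error of the batch).
#' @export
rbm_cd_update <- function(rbm, batch, learning_rate, k = 1L) {
  if (is.null(dim(batch))) batch <- matrix(batch, nrow = 1L)
  if (nrow(batch) == 0L) stop("empty batch", call. = FALSE)
  m <- nrow(batch)
  ph0 <- rbm_hidden_probs(rbm, batch)
  h <- matrix(rbinom(length(ph0), 1L, ph0), nrow = m)
  for (s in seq_len(k)) {
    pv <- rbm_visible_probs(rbm, h)
    ph <- rbm_hidden_probs(rbm, pv)
    if (s < k) h <- matrix(rbinom(length(ph), 1L, ph), nrow = m)
  }
  rbm$W <- rbm$W + learning_rate * (crossprod(batch, ph0) - crossprod(pv, ph)) / m
  rbm$b <- rbm$b + learning_rate * colMeans(batch - pv)
  rbm$c <- rbm$c + learning_rate * colMeans(ph0 - ph)
  attr(rbm, "recon_error") <- mean((batch - pv)^2)
  rbm
}

# Train one RBM for several epochs of mini-batch CD via the compiled inner
# loop; returns the rbm and a per-epoch mean reconstruction-error log. Uses
# the current RNG stream (shuffling in R, Gibbs sampling in C++).
rbm_train <- function(rbm, X, learning_rate, epochs, batch_size, k = 1L) {
  n <- nrow(X)
  log <- numeric(epochs)
  for (e in seq_len(epochs)) {
    perm <- sample.int(n)
    upd <- cpp_rbm_epoch(rbm$W, rbm$b, rbm$c, X, perm, learning_rate,
                         as.integer(batch_size), as.integer(k))
    rbm$W <- upd$W
    rbm$b <- as.numeric(upd$b)
    rbm$c <- as.numeric(upd$c)
    log[e] <- upd$recon_error
  }
  attr(rbm, "epoch_recon_error") <- log
  rbm
}
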