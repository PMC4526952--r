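# Independent oracles used across the suite. These re-derive quantities by
# brute force (full-state enumeration, hand sweeps) without touching the
# package's own computation paths.

# All 2^n binary configurations as rows of a matrix.
enumerate_states <- function(n) {
  if (n == 0L) return(matrix(0, 1L, 0L))
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))
}

# Unnormalized Boltzmann weight exp(b'v + c'h + v'Wh) for one (v, h) pair.
rbm_joint_weight <- function(W, b, cc, v, h) {
  exp(sum(b * v) + sum(cc * h) + as.numeric(t(v) %*% W %*% h))
}

# p(h_j = 1 | v) by summing the joint over all hidden states.
oracle_hidden_conditional <- function(W, b, cc, v) {
  H <- enumerate_states(length(cc))
  w <- apply(H, 1L, function(h) rbm_joint_weight(W, b, cc, v, h))
  unname(colSums(H * w) / sum(w))
}

# Exact mean log-likelihood of binary rows of V under the RBM, by full
# enumeration of the joint.
oracle_rbm_loglik <- function(W, b, cc, V) {
  nv <- length(b); nh <- length(cc)
  Vs <- enumerate_states(nv); Hs <- enumerate_states(nh)
  Z <- 0
  for (i in seq_len(nrow(Vs))) {
    for (j in seq_len(nrow(Hs))) {
      Z <- Z + rbm_joint_weight(W, b, cc, Vs[i, ], Hs[j, ])
    }
  }
  ll <- apply(V, 1L, function(v) {
    pv <- sum(apply(Hs, 1L, function(h) rbm_joint_weight(W, b, cc, v, h)))
    log(pv) - log(Z)
  })
  mean(ll)
}

# Exact gradient of the mean log-likelihood wrt W:
# E_data[v E[h|v]'] - E_model[v h'] by enumeration.
oracle_rbm_grad_W <- function(W, b, cc, V) {
  nv <- length(b); nh <- length(cc)
  Vs <- enumerate_states(nv); Hs <- enumerate_states(nh)
  pos <- matrix(0, nv, nh)
  for (i in seq_len(nrow(V))) {
    v <- V[i, ]
    eh <- oracle_hidden_conditional(W, b, cc, v)
    pos <- pos + outer(v, eh)
  }
  pos <- pos / nrow(V)
  neg <- matrix(0, nv, nh)
  Z <- 0
  for (i in seq_len(nrow(Vs))) {
    for (j in seq_len(nrow(Hs))) {
      w <- rbm_joint_weight(W, b, cc, Vs[i, ], Hs[j, ])
      neg <- neg + w * outer(Vs[i, ], Hs[j, ])
      Z <- Z + w
    }
  }
  pos - neg / Z
}

# Trapezoidal area under the (fall-out, recall) curve from a ROC sweep.
oracle_auc_trapezoid <- function(roc) {
  o <- order(roc$fallout, roc$recall)
  x <- c(roc$fallout[o], 1)
  y <- c(roc$recall[o], 1)
  if (x[1] != 0 || y[1] != 0) { x <- c(0, x); y <- c(0, y) }
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

# Build a tweet store in code without touching the JSON reader.
make_store <- function(texts,
                       times = seq_along(texts) * 3600,
                       users = sprintf("u%02d", seq_along(texts)),
                       hashtags = rep(list(character(0)), length(texts)),
                       has_url = rep(FALSE, length(texts)),
                       retweet_of = rep(NA_character_, length(texts)),
                       ids = sprintf("id%03d", seq_along(texts))) {
  tweetdbn:::new_tweet_store(
    id = ids, text = texts,
    created_at = as.POSIXct("2014-06-01", tz = "UTC") + times,
    screen_name = users, hashtags = hashtags, has_url = has_url,
    retweet_of = retweet_of)
}

# A stub trainer for cross_validate that always predicts `category`.
constant_trainer <- function(category, scheme = category_scheme()) {
  function(X_train, y_train) {
    function(X_new) {
      P <- matrix(1e-3, nrow(X_new), length(scheme),
                  dimnames = list(NULL, scheme))
      P[, category] <- 1 - 1e-3 * (length(scheme) - 1)
      P
    }
  }
}
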