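# Deep belief network classifier: a stack of Bernoulli RBMs greedily
# pretrained on unlabeled feature vectors, unrolled into a feed-forward
# network (sigmoid hidden layers, softmax output) and fine-tuned with
# mini-batch back-propagation under inverted dropout.

#' Pretraining configuration
#'
#' @param cd_k Gibbs steps per contrastive-divergence update (default 1).
#' @param learning_rate CD step size (default 0.05).
#' @param epochs_per_layer passes over the data per RBM layer (default 10).
#' @param batch_size mini-batch size (default 10).
#' @param seed integer seed.
#' @return a `pretrain_config` list.
#' @export
pretrain_config <- function(cd_k = 1L, learning_rate = 0.05,
                            epochs_per_layer = 10L, batch_size = 10L,
                            seed = 1L) {
  stopifnot(cd_k >= 1L, learning_rate >= 0, epochs_per_layer >= 0L,
            batch_size >= 1L)
  structure(list(cd_k = as.integer(cd_k), learning_rate = learning_rate,
                 epochs_per_layer = as.integer(epochs_per_layer),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Fine-tuning configuration
#'
#' @param batch_size mini-batch size (default 10).
#' @param epochs passes over the labeled data (default 200).
#' @param learning_rate SGD step size (default 0.1).
#' @param dropout_rate probability of masking each hidden unit during
#'   training (default 0.2; hidden layers only, inverted scaling so the
#'   deterministic prediction pass needs no rescaling). At the default
#'   mini-batch size of 10 heavier rates inject enough gradient variance to
#'   destabilize fine-tuning, so the default is deliberately light.
#' @param seed integer seed.
#' @return a `finetune_config` list.
#' @export
finetune_config <- function(batch_size = 10L, epochs = 200L,
                            learning_rate = 0.1, dropout_rate = 0.2,
                            seed = 1L) {
  stopifnot(batch_size >= 1L, epochs >= 0L, learning_rate >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "finetune_config")
}

#' Initialize a DBN with random weights
#'
#' @param sizes integer vector of layer sizes, input first and output last;
#'   the default architecture is input, 700, 700, 300, then one output unit
#'   per category.
#' @param scheme category scheme naming the output units.
#' @param init_sd weight initialization SD (default 0.01).
#' @return a `dbn_model`: list with `sizes`, `W` (list of weight matrices),
#'   `b` (list of bias vectors), `scheme`.
#' @export
dbn_init <- function(sizes, scheme = category_scheme(), init_sd = 0.01) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 3L) stop("need at least input, one hidden, and output layer", call. = FALSE)
  if (sizes[length(sizes)] != length(scheme)) {
    stop("output layer size must equal the number of categories", call. = FALSE)
  }
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = init_sd),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(sizes = sizes, W = W, b = b, scheme = scheme),
            class = "dbn_model")
}

#' Default layer sizes for a given input dimension
#'
#' @param input_dim feature dimension.
#' @param scheme category scheme.
#' @return integer vector `c(input_dim, 700, 700, 300, n_categories)`.
#' @export
dbn_default_sizes <- function(input_dim, scheme = category_scheme()) {
  c(as.integer(input_dim), 700L, 700L, 300L, length(scheme))
}

#' Greedy layer-wise RBM pretraining
#'
#' Trains one RBM per hidden layer: the first on the unlabeled feature
#' matrix, each subsequent one on the mean-field hidden probabilities of the
#' layer below. RBM weights and hidden biases seed the feed-forward stack;
#' the output layer stays randomly initialized. Per-layer, per-epoch mean
#' reconstruction errors are attached as attribute `pretrain_log`.
#'
#' @param X_unlabeled binary feature matrix.
#' @param sizes layer sizes (length >= 3, input first, output last).
#' @param cfg a [pretrain_config()].
#' @param scheme category scheme.
#' @return pretrained `dbn_model` (top layer untrained).
#' @export
pretrain_dbn <- function(X_unlabeled, sizes, cfg = pretrain_config(),
                         scheme = category_scheme()) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 3L) stop("size list must have at least 3 layers", call. = FALSE)
  if (ncol(X_unlabeled) != sizes[1L]) stop("input dimension mismatch", call. = FALSE)
  withr::with_seed(cfg$seed, {
    model <- dbn_init(sizes, scheme)
    n_rbm <- length(sizes) - 2L
    input <- X_unlabeled
    log <- list()
    for (l in seq_len(n_rbm)) {
      rbm <- rbm_init(sizes[l], sizes[l + 1L])
      if (cfg$epochs_per_layer > 0L) {
        rbm <- rbm_train(rbm, input, cfg$learning_rate, cfg$epochs_per_layer,
                         cfg$batch_size, cfg$cd_k)
        log[[l]] <- data.frame(layer = l,
                               epoch = seq_len(cfg$epochs_per_layer),
                               recon_error = attr(rbm, "epoch_recon_error"))
      }
      model$W[[l]] <- rbm$W
      model$b[[l]] <- rbm$c
      if (l < n_rbm) input <- rbm_hidden_probs(rbm, input)
    }
    attr(model, "pretrain_log") <- if (length(log)) do.call(rbind, log) else NULL
    model
  })
}

# forward pass returning all activations; masks: optional list of dropout
# masks (already scaled) for the hidden layers
dbn_forward <- function(model, X, masks = NULL) {
  L <- length(model$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    act <- sigmoid(sweep(A[[l]] %*% model$W[[l]], 2L, model$b[[l]], `+`))
    if (!is.null(masks)) act <- act * masks[[l]]
    A[[l + 1L]] <- act
  }
  Z <- sweep(A[[L]] %*% model$W[[L]], 2L, model$b[[L]], `+`)
  A[[L + 1L]] <- softmax_rows(Z)
  A
}

# mean cross-entropy loss of the softmax output against one-hot Y
dbn_loss <- function(model, X, Y, masks = NULL) {
  P <- dbn_forward(model, X, masks)[[length(model$W) + 1L]]
  -mean(rowSums(Y * log(pmax(P, 1e-300))))
}

# analytic gradients of dbn_loss; returns list(W = ..., b = ...)
dbn_gradients <- function(model, X, Y, masks = NULL) {
  L <- length(model$W)
  m <- nrow(X)
  A <- dbn_forward(model, X, masks)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (A[[L + 1L]] - Y) / m          # dLoss/dZ_out for mean CE
  for (l in L:1L) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      dA <- tcrossprod(delta, model$W[[l]])
      if (!is.null(masks)) dA <- dA * masks[[l - 1L]]
      delta <- dA * A[[l]] * (1 - A[[l]])
    }
  }
  list(W = gW, b = gb)
}

labels_to_onehot <- function(y, scheme) {
  idx <- match(y, scheme)
  if (anyNA(idx)) {
    stop(sprintf("labels outside the category scheme: %s",
                 paste(unique(y[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  Y <- matrix(0, length(idx), length(scheme))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Fine-tune a DBN with back-propagation and dropout
#'
#' Minimizes the cross-entropy of the softmax outputs by seeded mini-batch
#' gradient descent. During training each hidden unit is masked with
#' probability `dropout_rate` and surviving activations are scaled by
#' `1/(1 - dropout_rate)` (inverted dropout), so [predict_scores()] runs a
#' plain deterministic forward pass.
#'
#' @param model a `dbn_model` (typically from [pretrain_dbn()]).
#' @param X binary feature matrix of labeled tweets.
#' @param y category name per row of `X`.
#' @param cfg a [finetune_config()].
#' @return fine-tuned `dbn_model`.
#' @export
finetune_dbn <- function(model, X, y, cfg = finetune_config()) {
  if (nrow(X) != length(y)) stop("X rows must match length of y", call. = FALSE)
  if (ncol(X) != model$sizes[1L]) stop("input dimension mismatch", call. = FALSE)
  Y <- labels_to_onehot(y, model$scheme)
  n <- nrow(X)
  if (cfg$epochs == 0L) return(model)
  withr::with_seed(cfg$seed, {
    perms <- vapply(seq_len(cfg$epochs), function(e) sample.int(n), integer(n))
    upd <- cpp_finetune(model$W, model$b, X, Y, perms, cfg$learning_rate,
                        cfg$batch_size, cfg$dropout_rate)
    model$W <- upd$W
    model$b <- lapply(upd$b, as.numeric)
    model
  })
}

#' Per-category scores for a feature matrix
#'
#' Deterministic forward pass (no dropout sampling); each row of the result
#' is a softmax distribution over the scheme's categories and sums to 1.
#'
#' @param model a `dbn_model`.
#' @param X binary feature matrix.
#' @return score matrix (rows = tweets, columns named by the scheme).
#' @export
predict_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$sizes[1L]) stop("input dimension mismatch", call. = FALSE)
  P <- dbn_forward(model, X)[[length(model$W) + 1L]]
  colnames(P) <- model$scheme
  if (!is.null(rownames(X))) rownames(P) <- rownames(X)
  P
}

#' Save / load a DBN model
#'
#' Portable JSON container with a format version, layer sizes, category
#' scheme, and full-precision weights; `load_dbn(save_dbn(m))` restores the
#' model bit-identically.
#'
#' @param model a `dbn_model`.
#' @param path file path.
#' @return `load_dbn` returns the restored `dbn_model`.
#' @export
save_dbn <- function(model, path) {
  # doubles are stored as %.17g strings: enough digits to restore every
  # IEEE-754 value bit-identically through the JSON round trip
  payload <- list(
    format = "tweetdbn-model-1",
    sizes = model$sizes,
    scheme = model$scheme,
    W = lapply(model$W, function(w) sprintf("%.17g", as.vector(w))),
    b = lapply(model$b, function(v) sprintf("%.17g", v))
  )
  jsonlite::write_json(payload, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_dbn
#' @export
load_dbn <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file", call. = FALSE))
  if (!identical(as.character(obj$format), "tweetdbn-model-1")) {
    stop("unrecognized model file format/version", call. = FALSE)
  }
  sizes <- as.integer(obj$sizes)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l) {
    matrix(as.numeric(obj$W[[l]]), sizes[l], sizes[l + 1L])
  })
  b <- lapply(seq_len(L), function(l) as.numeric(obj$b[[l]]))
  structure(list(sizes = sizes, W = W, b = b, scheme = as.character(obj$scheme)),
            class = "dbn_model")
}
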