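# Deep belief network: pretraining, fine-tuning, prediction, persistence.

abc <- c("a", "b", "c")

tiny_labeled <- function(n = 60L, seed = 5L) {
  # two linearly separable classes over 10 binary features
  withr::with_seed(seed, {
    y <- rep(category_scheme()[1:2], length.out = n)
    X <- matrix(rbinom(n * 10L, 1L, 0.15), n, 10L)
    X[y == category_scheme()[1L], 1:3] <- 1
    X[y == category_scheme()[2L], 8:10] <- 1
    list(X = X, y = y)
  })
}

test_that("pretraining is seed-deterministic and logs reconstruction error", {
  set.seed(3)
  X <- matrix(rbinom(600L, 1L, 0.3), 60L, 10L)
  cfg <- pretrain_config(epochs_per_layer = 3L, seed = 17L)
  m1 <- pretrain_dbn(X, c(10L, 8L, 6L, 9L), cfg)
  m2 <- pretrain_dbn(X, c(10L, 8L, 6L, 9L), cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  log <- attr(m1, "pretrain_log")
  expect_identical(unique(log$layer), 1:2)
  expect_identical(nrow(log), 6L)
  expect_error(pretrain_dbn(X, c(10L, 9L), pretrain_config()), "3 layers")
})

test_that("layer-1 reconstruction error decreases over pretraining epochs", {
  gen <- generate_corpus(generator_config(n_days = 4L, base_rate = 100, seed = 23L,
                                          spike_days = data.frame(day = integer(0),
                                                                  multiplier = numeric(0))))
  spec <- feature_spec(unlist(tweetdbn:::default_signature_vocab(), use.names = FALSE))
  X <- featurize_tweets(gen$store, spec)
  m <- pretrain_dbn(X, c(spec$total_dim, 30L, 9L),
                    pretrain_config(epochs_per_layer = 8L, seed = 2L))
  log <- attr(m, "pretrain_log")
  l1 <- log$recon_error[log$layer == 1L]
  expect_lt(l1[length(l1)], l1[1L])
})

test_that("zero learning rate and zero epochs leave the model unchanged", {
  d <- tiny_labeled()
  set.seed(1)
  m <- dbn_init(c(10L, 6L, 9L))
  m_lr0 <- finetune_dbn(m, d$X, d$y, finetune_config(epochs = 3L, learning_rate = 0,
                                                     dropout_rate = 0, seed = 1L))
  expect_equal(m_lr0$W, m$W, tolerance = 1e-15)
  m_ep0 <- finetune_dbn(m, d$X, d$y, finetune_config(epochs = 0L, seed = 1L))
  expect_identical(m_ep0$W, m$W)
})

test_that("analytic back-propagation gradients match central finite differences", {
  set.seed(9)
  m <- dbn_init(c(6L, 5L, 4L, 3L), scheme = abc, init_sd = 0.5)
  X <- matrix(rbinom(30L, 1L, 0.5), 5L, 6L)
  Y <- diag(3L)[sample.int(3L, 5L, replace = TRUE), ]
  g <- tweetdbn:::dbn_gradients(m, X, Y)
  eps <- 1e-6
  for (l in 1:3) {
    idx <- cbind(sample.int(nrow(m$W[[l]]), 4L, TRUE),
                 sample.int(ncol(m$W[[l]]), 4L, TRUE))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      mp <- m; mp$W[[l]][i, j] <- mp$W[[l]][i, j] + eps
      mm <- m; mm$W[[l]][i, j] <- mm$W[[l]][i, j] - eps
      fd <- (tweetdbn:::dbn_loss(mp, X, Y) - tweetdbn:::dbn_loss(mm, X, Y)) / (2 * eps)
      an <- g$W[[l]][i, j]
      expect_lt(abs(fd - an) / max(abs(fd) + abs(an), 1e-8), 1e-5)
    }
  }
})

test_that("one full-batch compiled epoch equals one reference gradient step", {
  d <- tiny_labeled(n = 20L)
  set.seed(2)
  m <- dbn_init(c(10L, 7L, 5L, 9L), init_sd = 0.3)
  Y <- tweetdbn:::labels_to_onehot(d$y, m$scheme)
  g <- tweetdbn:::dbn_gradients(m, d$X, Y)
  ref_W1 <- m$W[[1L]] - 0.2 * g$W[[1L]]
  ref_W3 <- m$W[[3L]] - 0.2 * g$W[[3L]]
  fast <- finetune_dbn(m, d$X, d$y,
                       finetune_config(batch_size = 20L, epochs = 1L,
                                       learning_rate = 0.2, dropout_rate = 0,
                                       seed = 4L))
  expect_equal(fast$W[[1L]], ref_W1, tolerance = 1e-12)
  expect_equal(fast$W[[3L]], ref_W3, tolerance = 1e-12)
})

test_that("fine-tuning is seed-deterministic with dropout", {
  d <- tiny_labeled()
  set.seed(6)
  m0 <- dbn_init(c(10L, 8L, 9L))
  cfg <- finetune_config(epochs = 4L, dropout_rate = 0.3, seed = 12L)
  m1 <- finetune_dbn(m0, d$X, d$y, cfg)
  m2 <- finetune_dbn(m0, d$X, d$y, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
})

test_that("a separable two-class problem trains to high accuracy", {
  d <- tiny_labeled(n = 80L)
  set.seed(8)
  m <- dbn_init(c(10L, 12L, 9L))
  m <- finetune_dbn(m, d$X, d$y, finetune_config(epochs = 200L, seed = 3L))
  acc <- multiclass_accuracy(assign_categories(predict_scores(m, d$X)), d$y)
  expect_gte(acc, 0.95)
})

test_that("prediction rows are softmax distributions", {
  set.seed(4)
  m <- dbn_init(c(7L, 5L, 9L), init_sd = 0.6)
  X <- matrix(rbinom(70L, 1L, 0.5), 10L, 7L)
  P <- predict_scores(m, X)
  expect_equal(unname(rowSums(P)), rep(1, 10L), tolerance = 1e-9)
  expect_true(all(P > 0 & P < 1))
  expect_identical(colnames(P), category_scheme())
  # zero weights give uniform scores
  m$W <- lapply(m$W, function(w) { w[] <- 0; w })
  m$b <- lapply(m$b, function(v) { v[] <- 0; v })
  expect_equal(unname(predict_scores(m, X)[1L, ]), rep(1 / 9, 9L))
  expect_error(predict_scores(m, X[, 1:3]), "dimension")
})

test_that("a hand-built 2-2-2 network reproduces hand-computed arithmetic", {
  m <- structure(list(
    sizes = c(2L, 2L, 2L),
    W = list(matrix(c(1, -1, 0.5, 2), 2L, 2L), matrix(c(1, 0, -1, 1), 2L, 2L)),
    b = list(c(0.1, -0.2), c(0, 0.3)),
    scheme = c("x", "y")), class = "dbn_model")
  v <- c(1, 0)
  h <- 1 / (1 + exp(-(c(1, 0.5) * 1 + c(-1, 2) * 0 + c(0.1, -0.2))))
  z <- c(h[1L] * 1 + h[2L] * 0 + 0, h[1L] * -1 + h[2L] * 1 + 0.3)
  p <- exp(z) / sum(exp(z))
  expect_equal(unname(predict_scores(m, v)[1L, ]), p, tolerance = 1e-12)
})

test_that("models survive a save/load round trip bit-identically", {
  set.seed(10)
  m <- dbn_init(c(6L, 4L, 9L), init_sd = 0.7)
  f <- withr::local_tempfile(fileext = ".json")
  save_dbn(m, f)
  back <- load_dbn(f)
  expect_identical(back$W, m$W)
  expect_identical(back$b, m$b)
  expect_identical(back$scheme, m$scheme)
  X <- matrix(rbinom(30L, 1L, 0.5), 5L, 6L)
  expect_identical(predict_scores(back, X), predict_scores(m, X))
  # truncated file fails to load
  txt <- readLines(f)
  writeLines(substr(paste(txt, collapse = ""), 1L, 50L), f)
  expect_error(load_dbn(f), "parse|format")
})
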