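# Network layers, loss, gradients, training and prediction.

test_that("convolution matches hand-computed values and lengths", {
  # zero filter: all scores zero
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(convolve_filter(X, matrix(0, 2, 4), 0), rep(0, 4))
  # all-ones input (width 4), w = 2, all-ones filter, b = -3:
  # every window sums to 8, so each score is relu(8 - 3) = 5
  X1 <- matrix(1, 4, 4)
  expect_equal(convolve_filter(X1, matrix(1, 2, 4), b = -3), rep(5, 3))
  # score-sequence length is n - w + 1
  Xn <- matrix(0, 128, 3)
  expect_length(convolve_filter(Xn, matrix(0, 6, 3)), 123)
  expect_error(convolve_filter(matrix(0, 3, 2), matrix(0, 5, 2)),
               "exceeds")
})

test_that("max pooling: basics, permutation invariance, monotonicity", {
  expect_equal(pool_max(c(0, 5, 3)), 5)
  expect_equal(pool_max(rep(2.5, 7)), 2.5)
  expect_error(pool_max(numeric(0)), "empty")
  set.seed(1)
  for (rep in 1:20) {
    s <- rnorm(15)
    expect_equal(pool_max(sample(s)), pool_max(s))
    bump <- s; i <- sample.int(15, 1); bump[i] <- bump[i] + abs(rnorm(1))
    expect_gte(pool_max(bump), pool_max(s))
  }
})

test_that("batched forward agrees with the single-filter reference path", {
  ts <- tiny_setup()
  model <- init_cnn(ts$vocab, ts$hyper)
  tr <- cnn_forward(model, ts$enc, rows = 1:3)
  d <- ts$hyper$me + 2 * ts$hyper$md
  for (b in 1:3) {
    X <- input_matrix(ts$enc, b, model$params)
    z_ref <- unlist(lapply(ts$hyper$filter_sizes, function(w) {
      Fw <- model$params[[paste0("F_", w)]]
      bw <- model$params[[paste0("b_", w)]]
      vapply(seq_len(ts$hyper$m), function(f) {
        pool_max(convolve_filter(
          X, matrix(Fw[f, ], w, d, byrow = TRUE), bw[f]))
      }, numeric(1))
    }))
    expect_equal(unname(tr$z[b, ]), unname(z_ref), tolerance = 1e-12)
  }
})

test_that("dropout limits: all-ones mask equals eval; probabilities sum to 1", {
  ts <- tiny_setup()
  model <- init_cnn(ts$vocab, ts$hyper)
  mtot <- ts$hyper$m * length(ts$hyper$filter_sizes)
  ones <- matrix(1, 4, mtot)
  tr_train <- cnn_forward(model, ts$enc, 1:4, mode = "train",
                          dropout_mask = ones)
  tr_eval <- cnn_forward(model, ts$enc, 1:4, mode = "eval")
  expect_equal(tr_train$prob, tr_eval$prob)
  for (seed in 1:5) {
    m <- init_cnn(ts$vocab, hyperparams(n = 8, me = 4, md = 2,
                                        filter_sizes = c(2, 3), m = 3,
                                        seed = seed))
    pr <- cnn_forward(m, ts$enc)$prob
    expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
    expect_true(all(pr >= 0))
  }
})

test_that("a zero softmax layer yields uniform probabilities of 0.2", {
  ts <- tiny_setup()
  model <- init_cnn(ts$vocab, ts$hyper)
  model$params$Ws[] <- 0
  model$params$d[] <- 0
  pr <- cnn_forward(model, ts$enc, 1:4)$prob
  expect_equal(unname(pr), matrix(0.2, 4, 5), tolerance = 1e-12)
})

test_that("loss: perfect prediction ~0, uniform predictor N log 5", {
  ts <- tiny_setup()
  model <- init_cnn(ts$vocab, ts$hyper)
  model$params$Ws[] <- 0
  model$params$d[] <- 0
  N <- length(ts$inst)
  expect_equal(cnn_loss(model, ts$enc), N * log(5), tolerance = 1e-10)
  # pin nearly all mass on one class and evaluate on that class only
  rows_adv <- which(ts$enc$label == 1L)
  model$params$d[1] <- 60
  expect_lt(cnn_loss(model, ts$enc, rows_adv), 1e-6)
})

test_that("loss on a fixed batch with a fixed mask is bit-reproducible", {
  ts <- tiny_setup()
  model <- init_cnn(ts$vocab, ts$hyper)
  set.seed(10)
  mask <- matrix((runif(4 * 6) >= 0.5) / 0.5, 4, 6)
  l1 <- cnn_loss(model, ts$enc, 1:4, dropout_mask = mask)
  l2 <- cnn_loss(model, ts$enc, 1:4, dropout_mask = mask)
  expect_identical(l1, l2)
})

test_that("analytic gradients match central differences on a tiny model", {
  # tiny configuration: n = 6, me = 4, md = 2, w in {2, 3}, m = 3
  ts <- tiny_setup(n = 6, me = 4, md = 2, filter_sizes = c(2, 3), m = 3,
                   seed = 5, l2 = 0.5)
  model <- init_cnn(ts$vocab, ts$hyper)
  set.seed(17)
  mtot <- 6
  rows <- 1:5
  mask <- matrix((runif(length(rows) * mtot) >= 0.5) / 0.5,
                 length(rows), mtot)
  grads <- cnn_gradients(model, ts$enc, rows, dropout_mask = mask)
  for (nm in names(grads)) {
    ng <- numeric_gradient(model, nm, ts$enc, rows, mask)
    rel <- max(abs(ng - grads[[nm]]) /
                 pmax(abs(ng), abs(grads[[nm]]), 1e-8))
    expect_lt(rel, 1e-4, label = paste("relative gradient error for", nm))
  }
})

test_that("training is reproducible and epochs = 0 is a no-op", {
  ts <- tiny_setup()
  hy <- hyperparams(n = 8, me = 4, md = 2, filter_sizes = c(2, 3), m = 3,
                    batch_size = 4, epochs = 3, seed = 5)
  m1 <- train_cnn(ts$inst, hy)
  m2 <- train_cnn(ts$inst, hy)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$curve), 3)
  expect_equal(m1$updates, 3 * ceiling(length(ts$inst) / 4))

  hy0 <- hyperparams(n = 8, me = 4, md = 2, filter_sizes = c(2, 3),
                     m = 3, epochs = 0, seed = 5)
  m0 <- train_cnn(ts$inst, hy0)
  expect_identical(m0$params, init_cnn(ts$vocab, hy0)$params)
  expect_equal(nrow(m0$curve), 0)
})

test_that("a large l2 coefficient pulls the softmax norm down monotonically", {
  ts <- tiny_setup()
  hy <- hyperparams(n = 8, me = 4, md = 2, filter_sizes = c(2, 3), m = 3,
                    batch_size = 4, epochs = 5, l2 = 50, seed = 5)
  m <- train_cnn(ts$inst, hy)
  norms <- m$curve$ws_norm
  expect_true(all(diff(norms) < 0))
})

test_that("prediction: argmax, lowest-index tie-break, batch invariance", {
  ts <- tiny_setup()
  model <- init_cnn(ts$vocab, ts$hyper)
  # uniform probabilities tie-break to the first class
  tied <- model
  tied$params$Ws[] <- 0; tied$params$d[] <- 0
  expect_true(all(predict_cnn(tied, ts$enc, type = "index") == 1L))
  # argmax on a shifted bias
  tied$params$d <- c(0, 3, 0, 0, 0)
  expect_true(all(predict_cnn(tied, ts$enc) == "effect"))
  # partition invariance
  p_all <- predict_cnn(model, ts$enc, type = "prob")
  p_small <- predict_cnn(model, ts$enc, type = "prob", batch_size = 3)
  expect_equal(p_all, p_small)
})

test_that("training separates the cue-labelled toy task", {
  ts <- tiny_setup()
  hy <- hyperparams(n = 8, me = 12, md = 2, filter_sizes = c(2, 3),
                    m = 8, batch_size = 5, epochs = 30, dropout = 0.2,
                    l2 = 0.1, lr = 5e-3, seed = 11)
  m <- train_cnn(ts$inst, hy)
  expect_gte(tail(m$curve$train_f1, 1), 99)
})

test_that("checkpoints round-trip bit-identically", {
  ts <- tiny_setup()
  hy <- hyperparams(n = 8, me = 4, md = 2, filter_sizes = c(2, 3), m = 3,
                    epochs = 2, batch_size = 4, seed = 5)
  m <- train_cnn(ts$inst, hy)
  path <- withr::local_tempfile(fileext = ".rds")
  save_cnn(m, path)
  back <- load_cnn(path)
  expect_identical(back$params, m$params)
  expect_identical(back$vocab, m$vocab)
  expect_identical(back$hyper, m$hyper)
  expect_equal(predict_cnn(back, ts$enc, type = "prob"),
               predict_cnn(m, ts$enc, type = "prob"))
})
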