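test_that("probabilities are normalised and initialisation is seeded", {
  m <- build_model(cnn_architecture(), seed = 4)
  m2 <- build_model(cnn_architecture(), seed = 4)
  expect_identical(m$weights, m2$weights)
  m3 <- build_model(cnn_architecture(), seed = 5)
  expect_false(identical(m$weights, m3$weights))

  set.seed(1)
  x <- array(runif(7 * 64 * 64 * 3, 0, 255), c(7, 64, 64, 3))
  probs <- tubulequant:::cpp_cnn_forward(
    x, m$weights, tubulequant:::conv_matrix(m$architecture),
    m$architecture$fc_widths, scale = 255)
  expect_equal(dim(probs), c(7, 2))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-6)
})

test_that("parameter count matches the closed-form layer arithmetic", {
  arch <- cnn_architecture()
  # 64 ->(3x3)62 ->/2 31 ->29 ->/2 14 ->12 ->/2 6 ; flat = 6*6*24
  by_hand <- (9 * 3 * 6 + 6) + (9 * 6 * 12 + 12) + (9 * 12 * 24 + 24) +
    (6 * 6 * 24 * 32 + 32) + (32 * 2 + 2)
  expect_equal(n_parameters(arch), by_hand)

  wide <- cnn_architecture(conv_blocks = list(c(4, 5, 3)), fc_widths = c(10, 2))
  # 64 ->(5x5)60 ->/3 20 ; flat = 20*20*4
  expect_equal(n_parameters(wide),
               (25 * 3 * 4 + 4) + (20 * 20 * 4 * 10 + 10) + (10 * 2 + 2))
  # stored weight tensors add up to the same count
  m <- build_model(arch, seed = 1)
  expect_equal(sum(vapply(m$weights, length, 0L)), n_parameters(arch))
})

test_that("architecture contracts are validated", {
  expect_error(cnn_architecture(conv_blocks = list()), "at least one")
  expect_error(cnn_architecture(fc_widths = c(16, 3)), "ending in 2")
  expect_error(cnn_architecture(fc_widths = c(16, 8, 2)), "ending in 2")
  expect_error(build_model(cnn_architecture(input_size = 32)), "64 x 64")
  expect_error(
    cnn_architecture(conv_blocks = list(c(4, 33, 2), c(4, 33, 2))),
    "collapses")
})

test_that("backpropagation gradients match finite differences", {
  conv <- matrix(c(2L, 3L, 2L, 3L, 3L, 1L), 2, 3, byrow = TRUE)
  fc <- c(4L, 2L)
  set.seed(7)
  # input 12x12x2: block1 -> 5x5x2, block2 -> 3x3x3, flat 27
  w <- list(matrix(rnorm(18 * 2, 0, 0.4), 18, 2), rep(0, 2),
            matrix(rnorm(18 * 3, 0, 0.4), 18, 3), rnorm(3, 0, 0.1),
            matrix(rnorm(27 * 4, 0, 0.4), 27, 4), rep(0, 4),
            matrix(rnorm(8, 0, 0.4), 4, 2), rep(0, 2))
  x <- array(rnorm(3 * 12 * 12 * 2), c(3, 12, 12, 2))
  y <- c(1L, 0L, 1L)
  sw <- c(1, 0.5, 2)   # non-uniform sample weights exercise weighting too
  lg <- tubulequant:::cpp_cnn_loss_grad(x, y, w, conv, fc, w = sw, scale = 1)
  loss_at <- function(wmod) {
    tubulequant:::cpp_cnn_loss_grad(x, y, wmod, conv, fc, w = sw,
                                    scale = 1)$loss
  }
  eps <- 1e-6
  for (k in seq_along(w)) {
    for (i in sample(length(w[[k]]), min(4, length(w[[k]])))) {
      wp <- w; wp[[k]][i] <- wp[[k]][i] + eps
      wm <- w; wm[[k]][i] <- wm[[k]][i] - eps
      numeric_grad <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_lt(abs(lg$grads[[k]][i] - numeric_grad), 1e-6)
    }
  }
})

test_that("prediction is order-preserving, duplicate- and batch-invariant", {
  m <- build_model(cnn_architecture(), seed = 11)
  set.seed(2)
  x <- array(runif(5 * 64 * 64 * 3, 0, 255), c(5, 64, 64, 3))
  x[3, , , ] <- x[1, , , ]   # duplicated patch
  p <- predict_tubule_prob(m, x)
  expect_length(p, 5)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[3], p[1])
  # batch-of-1 equals batch-of-n
  p1 <- predict_tubule_prob(m, x[2, , , ])
  expect_equal(p1, p[2], tolerance = 1e-5)
  expect_error(predict_tubule_prob(m, array(0, c(2, 32, 32, 3))), "64")
})

test_that("thresholding is strict and validates its domain", {
  expect_equal(classify_tubule(c(0.51, 0.5, 0, 1)),
               c("tubule", "non_tubule", "non_tubule", "tubule"))
  expect_equal(classify_tubule(0.7, threshold = 0.7), "non_tubule")
  expect_error(classify_tubule(1.2), "\\[0, 1\\]")
  expect_error(classify_tubule(-0.1), "\\[0, 1\\]")
})

test_that("training separates the synthetic task and is reproducible", {
  learn <- tubule_patch_set()
  cfg <- train_config(seed = 12)   # default epochs and patch cap
  model <- build_model(cnn_architecture(), seed = 12)
  fit <- train_classifier(model, learn$patches, learn$labels, cfg)
  expect_true(fit$trained)
  # loss decreases over epochs (trend)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  # training accuracy on the patches the fit saw is high
  prob <- predict_tubule_prob(fit, learn$patches)
  acc <- mean(classify_tubule(prob) == learn$labels)
  expect_gte(acc, 0.95)
  # identical seed and data -> identical weights (short run suffices)
  small <- train_config(epochs = 1, max_train_patches = 200, seed = 5)
  refit1 <- train_classifier(model, learn$patches, learn$labels, small)
  refit2 <- train_classifier(model, learn$patches, learn$labels, small)
  expect_identical(refit1$weights, refit2$weights)

  # single-class training sets are rejected
  idx <- which(learn$labels == "non_tubule")[1:40]
  expect_error(
    train_classifier(model, learn$patches[idx, , , , drop = FALSE],
                     learn$labels[idx], cfg),
    class = "tubulequant_single_class")
})

test_that("oversampling presents balanced classes each epoch", {
  y <- c(rep(1L, 3), rep(0L, 17))
  withr::with_seed(1, {
    for (rep in 1:5) {
      idx <- tubulequant:::balance_indices(y)
      expect_equal(sum(y[idx] == 1L), sum(y[idx] == 0L))
      expect_true(all(which(y == 0L) %in% idx))
    }
  })
  # already balanced data is passed through untouched
  expect_equal(tubulequant:::balance_indices(c(0L, 1L, 0L, 1L)), 1:4)
})

test_that("checkpoints round-trip through JSON", {
  m <- build_model(cnn_architecture(conv_blocks = list(c(3, 5, 4)),
                                    fc_widths = c(8, 2)), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(m, path)
  back <- read_classifier(path)
  expect_equal(back$architecture$conv_blocks, m$architecture$conv_blocks)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  set.seed(3)
  x <- array(runif(2 * 64 * 64 * 3, 0, 255), c(2, 64, 64, 3))
  expect_equal(predict_tubule_prob(back, x), predict_tubule_prob(m, x),
               tolerance = 1e-10)
})
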