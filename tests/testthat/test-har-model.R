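test_that("encoder feature lengths follow the pooling ladder", {
  cfg <- unet_config(n_classes = 5)
  expect_equal(unet_feature_lengths(cfg, 64), c(64, 32, 16, 8, 4))
  # lengths not divisible by the pool ladder are padded internally
  expect_equal(unet_internal_length(cfg, 25), 32L)
  expect_equal(unet_feature_lengths(cfg, 25), c(32, 16, 8, 4, 2))
})

test_that("config validation rejects inconsistent architectures", {
  expect_error(unet_config(decoder_filters = c(1, 2, 3)), "one entry fewer")
  expect_error(unet_config(kernel = 4), "odd")
  expect_error(unet_config(pool = 2, upsample = 3), "match")
  expect_error(unet_config(n_classes = 1), "at least 2 classes")
  expect_error(build_fcn(1, 5, "A"), "at least 2 classes")
})

test_that("U-Net output length equals input length for admissible window sizes", {
  cfg <- tiny_unet_cfg()
  for (W in c(16, 32, 64, 128)) {
    m <- build_unet(cfg, W, vocab_size = 10, classes = c("A", "B", "C"),
                    seed = 2)
    idx <- matrix(sample(0:11, 2 * W, replace = TRUE), 2, W)
    out <- habitminer:::model_forward(m, idx)
    expect_equal(dim(out$per_position), c(2, unet_internal_length(cfg, W), 3))
    # softmax normalization at every position
    sums <- apply(out$per_position, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
    expect_equal(dim(out$probs), c(2, 3))
    expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6))
  }
})

test_that("depth scaling shrinks the printed architecture as expected", {
  cfg <- unet_config(n_classes = 5, depth_scale = 0.125)
  expect_equal(cfg$encoder_filters, c(8L, 16L, 32L, 64L, 128L))
  expect_equal(cfg$decoder_filters, c(64L, 32L, 16L, 8L))
  small <- build_unet(cfg, 32, vocab_size = 20, classes = letters[1:5],
                      seed = 1)
  full <- build_unet(unet_config(n_classes = 5), 32, vocab_size = 20,
                     classes = letters[1:5], seed = 1)
  expect_lt(count_params(small) / count_params(full), 1 / 50)
})

test_that("the FCN follows the printed three-block filter/kernel layout", {
  m <- build_fcn(4, vocab_size = 8, classes = letters[1:4], seed = 1)
  expect_equal(m$cfg$layer_spec, list(c(128L, 8L), c(256L, 5L), c(128L, 3L)))
  expect_equal(dim(m$params$conv1$W), c(8 * 64, 128))
  expect_equal(dim(m$params$conv2$W), c(5 * 128, 256))
  expect_equal(dim(m$params$conv3$W), c(3 * 256, 128))
  idx <- matrix(sample(0:9, 3 * 25, replace = TRUE), 3, 25)
  out <- habitminer:::model_forward(m, idx)
  expect_equal(dim(out$probs), c(3, 4))
  expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6))
})

test_that("the LSTM uses 64 units and survives an all-padding window", {
  m <- build_lstm(3, vocab_size = 6, classes = c("A", "B", "C"), seed = 1)
  expect_equal(m$cfg$units, 64L)
  idx <- matrix(0L, 1, 10)      # all padding
  out <- habitminer:::model_forward(m, idx)
  expect_true(all(is.finite(out$probs)))
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(99)
  idx <- matrix(sample(1:6, 40 * 8, replace = TRUE), 40, 8)
  lab <- sample(c("A", "B"), 40, replace = TRUE)
  w <- structure(list(x = idx, label = lab, end_timestamp = NULL,
                      W = 8L, step = 1L), class = "event_windows")
  fit <- function() {
    m <- build_lstm(2, 6, c("A", "B"), units = 8, embed_dim = 4, seed = 7)
    train_with_early_stopping(m, w, w, epochs = 3, patience = 3, seed = 7)
  }
  h1 <- fit()$history; h2 <- fit()$history
  expect_identical(h1, h2)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(3)
  V <- 9; B <- 3; W <- 8
  idx <- matrix(sample(0:(V + 1), B * W, replace = TRUE), B, W)
  idx[1, 1:3] <- 0L                    # padded prefix
  y <- sample(1:3, B, replace = TRUE)
  cls <- c("A", "B", "C")
  m_unet <- build_unet(tiny_unet_cfg(), W, V, cls, seed = 3)
  expect_lt(grad_check(m_unet, idx, y), 1e-4)
  m_unet1 <- build_unet(tiny_unet_cfg(), W, V, cls, embedding = FALSE, seed = 3)
  expect_lt(grad_check(m_unet1, idx, y), 1e-4)
  m_fcn <- build_fcn(3, V, cls, embed_dim = 6, depth_scale = 0.05, seed = 4)
  expect_lt(grad_check(m_fcn, idx, y), 1e-4)
  m_lstm <- build_lstm(3, V, cls, units = 7, embed_dim = 5, seed = 5)
  expect_lt(grad_check(m_lstm, idx, y), 1e-4)
})

test_that("per-position pooling averages probabilities and breaks ties low", {
  pp <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.9, 0.1))
  expect_equal(pool_position_probs(pp, classes = c("A", "B")), "A")
  # uniform probabilities tie -> lowest class index
  ppu <- matrix(1 / 3, nrow = 4, ncol = 3)
  expect_equal(pool_position_probs(ppu), 1L)
  # masked positions are excluded from the mean
  pp2 <- rbind(c(1, 0), c(0, 1), c(0, 1))
  expect_equal(pool_position_probs(pp2, mask = c(1, 0, 0)), 1L)
  expect_equal(pool_position_probs(pp2, mask = c(0, 1, 1)), 2L)
})

test_that("prediction rejects indices beyond the embedding table", {
  m <- build_lstm(2, vocab_size = 4, classes = c("A", "B"), units = 4,
                  embed_dim = 3, seed = 1)
  expect_error(predict_windows(m, matrix(9L, 1, 5)), "beyond the embedding")
})

test_that("a one-class-dominated fit predicts that class", {
  set.seed(11)
  idx <- matrix(sample(1:4, 30 * 6, replace = TRUE), 30, 6)
  w <- structure(list(x = idx, label = rep(c("A", "B"), c(28, 2)),
                      end_timestamp = NULL, W = 6L, step = 1L),
                 class = "event_windows")
  m <- build_fcn(2, 4, c("A", "B"), embed_dim = 4, depth_scale = 0.05, seed = 2)
  m <- train_with_early_stopping(m, w, w, epochs = 5, patience = 5, seed = 2)
  pred <- predict_windows(m, w)
  expect_gt(mean(pred$label == "A"), 0.9)
})

test_that("checkpoints round-trip weights and predictions exactly", {
  m <- build_unet(tiny_unet_cfg(), 8, 5, c("A", "B", "C"), seed = 6)
  f <- tempfile(fileext = ".json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  idx <- matrix(sample(0:6, 2 * 8, replace = TRUE), 2, 8)
  expect_equal(predict_windows(m2, idx)$probs, predict_windows(m, idx)$probs,
               tolerance = 1e-12)
})
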