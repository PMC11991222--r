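test_that("stratified split keeps class proportions in the test set", {
  labels <- rep(c("A", "B", "C"), each = 100)
  sp <- split_and_fold(labels, seed = 4)
  expect_equal(length(sp$test_idx), 90)
  per_class <- table(labels[sp$test_idx])
  expect_true(all(abs(per_class - 30) <= 1))
  expect_equal(sort(unique(sp$fold)), 1:3)
  # folds are themselves stratified to within one window per class
  for (f in 1:3) {
    tf <- table(labels[sp$train_idx[sp$fold == f]])
    expect_true(all(abs(tf - 70 / 3) <= 1))
  }
})

test_that("split is deterministic under a fixed seed and errors on tiny classes", {
  labels <- rep(c("A", "B"), c(50, 30))
  s1 <- split_and_fold(labels, seed = 7)
  s2 <- split_and_fold(labels, seed = 7)
  expect_identical(s1, s2)
  expect_error(split_and_fold(c("A", "A", "A", "B", "B"), folds = 3), "B")
})

test_that("early stopping halts after patience epochs and keeps the best", {
  tr <- early_stop_trace(c(1.0, 0.8, 0.9, 0.95, 0.97), patience = 2)
  expect_equal(tr$stop_epoch, 4)
  expect_equal(tr$best_epoch, 2)
  # monotonically decreasing loss -> run to the end
  tr2 <- early_stop_trace(c(5, 4, 3, 2, 1), patience = 2)
  expect_equal(tr2$stop_epoch, 5)
  expect_equal(tr2$best_epoch, 5)
  expect_error(early_stop_trace(c(1, 2), patience = 0), "patience")
})

test_that("the training loop's checkpoint is never worse than any epoch seen", {
  set.seed(21)
  idx <- matrix(sample(1:5, 60 * 6, replace = TRUE), 60, 6)
  lab <- ifelse(idx[, 6] <= 2, "A", "B")
  w <- structure(list(x = idx, label = lab, end_timestamp = NULL,
                      W = 6L, step = 1L), class = "event_windows")
  m <- build_lstm(2, 5, c("A", "B"), units = 6, embed_dim = 4, seed = 3)
  m <- train_with_early_stopping(m, w, w, epochs = 6, patience = 2, seed = 3)
  expect_equal(min(m$history$val_loss),
               m$history$val_loss[m$best_epoch])
  expect_error(train_with_early_stopping(m, w, w, patience = 0), "patience")
})

test_that("metric formulas match hand-computed confusion matrices", {
  # perfect predictions
  r <- evaluate_predictions(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(r$weighted_f1, 100)
  expect_equal(r$balanced_accuracy, 100)
  # confusion [[9,1],[4,6]]: recalls 0.9 and 0.6
  truth <- rep(c("A", "B"), c(10, 10))
  pred <- c(rep("A", 9), "B", rep("A", 4), rep("B", 6))
  r2 <- evaluate_predictions(truth, pred)
  expect_equal(r2$balanced_accuracy, 75)
  expect_equal(as.vector(r2$confusion), c(9, 4, 1, 6))
  # constant predictor on a balanced binary set sits at chance
  r3 <- evaluate_predictions(rep(c("A", "B"), 5), rep("A", 10))
  expect_equal(r3$balanced_accuracy, 50)
  expect_error(evaluate_predictions(character(0), character(0)), "empty")
})

test_that("metrics agree with an independent reimplementation on random data", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(20:100, 1)
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    classes <- letters[1:k]
    r <- suppressWarnings(evaluate_predictions(truth, pred, classes))
    # independent route: per-class tallies computed directly
    f1s <- recs <- sups <- numeric(0)
    for (cl in classes) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      if (tp + fn == 0) next
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- tp / (tp + fn)
      f1s <- c(f1s, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
      recs <- c(recs, rec)
      sups <- c(sups, tp + fn)
    }
    expect_equal(r$weighted_f1, 100 * sum(sups / sum(sups) * f1s),
                 tolerance = 1e-9)
    expect_equal(r$balanced_accuracy, 100 * mean(recs), tolerance = 1e-9)
  }
})

test_that("classes absent from the test set are excluded with a warning", {
  expect_warning(
    r <- evaluate_predictions(c("A", "A"), c("A", "B"),
                              classes = c("A", "B", "C")),
    "absent")
  expect_equal(r$balanced_accuracy, 50)  # only A present, recall 1/2
})
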