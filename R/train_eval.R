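# Training protocol and evaluation metrics: stratified 70/30 split with
# stratified 3-fold cross-validation inside the training portion, early
# stopping on validation loss, weighted F1 and balanced accuracy (both in
# percent).

#' Stratified outer split and inner fold assignment
#'
#' Windows are shuffled, split 70/30 per class (stratified), and the
#' training portion is assigned to \code{folds} stratified
#' cross-validation folds. Deterministic for a fixed seed. Note that
#' shuffling overlapping sliding windows leaks near-duplicates across
#' splits; \code{scheme = "temporal"} instead takes the chronologically
#' last 30\% of each class as the test set.
#'
#' @param labels character vector of window labels
#' @param train_frac training fraction (default 0.70)
#' @param folds number of CV folds (default 3)
#' @param seed RNG seed
#' @param scheme \code{"shuffle"} (default) or \code{"temporal"}
#' @return list with \code{train_idx}, \code{test_idx}, and \code{fold}
#'   (integer fold id per training index, parallel to \code{train_idx})
#' @export
split_and_fold <- function(labels, train_frac = 0.70, folds = 3, seed = 1L,
                           scheme = c("shuffle", "temporal")) {
  scheme <- match.arg(scheme)
  tab <- table(labels)
  small <- names(tab)[tab < folds]
  if (length(small))
    stop("class(es) with fewer members than folds: ",
         paste(small, collapse = ", "))
  set.seed(seed)
  train_idx <- integer(0); test_idx <- integer(0); fold <- integer(0)
  for (cl in sort(names(tab))) {
    ix <- which(labels == cl)
    if (scheme == "shuffle") ix <- ix[sample.int(length(ix))]
    n_tr <- round(length(ix) * train_frac)
    n_tr <- max(folds, min(n_tr, length(ix) - 1))
    tr <- ix[seq_len(n_tr)]
    te <- ix[-seq_len(n_tr)]
    train_idx <- c(train_idx, tr)
    test_idx <- c(test_idx, te)
    fold <- c(fold, rep_len(seq_len(folds), n_tr))
  }
  o <- sample.int(length(train_idx))   # interleave classes within batches
  list(train_idx = train_idx[o], test_idx = sort(test_idx), fold = fold[o])
}

#' Early-stopping bookkeeping over a validation-loss trace
#'
#' Training stops once the validation loss has failed to improve on the
#' best value for \code{patience} consecutive epochs; the best epoch is
#' the one with minimum validation loss.
#'
#' @param val_losses numeric vector, one validation loss per epoch
#' @param patience epochs without improvement tolerated (>= 1)
#' @return list(stop_epoch, best_epoch): \code{stop_epoch} is the number
#'   of epochs actually run
#' @export
early_stop_trace <- function(val_losses, patience) {
  if (patience < 1) stop("patience must be at least 1")
  best <- Inf; best_epoch <- 0L; bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

.batch_loss <- function(model, x, y) {
  n <- nrow(x); tot <- 0
  for (s in seq(1, n, by = 256)) {
    e <- min(n, s + 255)
    out <- model_forward(model, x[s:e, , drop = FALSE], y[s:e])
    tot <- tot + out$loss * (e - s + 1)
  }
  tot / n
}

#' Train a model with early stopping on validation loss
#'
#' Minibatch Adam on cross-entropy (per-position, padding-masked, for the
#' U-Net; per-window for FCN/LSTM). After each epoch the validation loss
#' is computed; training stops when it has not improved for
#' \code{patience} epochs and the parameters from the best epoch are
#' restored.
#'
#' @param model a \code{har_model}
#' @param windows an \code{event_windows} with training data
#' @param val_windows an \code{event_windows} used for early stopping
#' @param epochs maximum epochs
#' @param patience early-stopping patience (default 5)
#' @param batch_size minibatch size (default 64)
#' @param lr Adam learning rate (default 1e-3)
#' @param seed RNG seed for batch shuffling
#' @param verbose print one line per epoch
#' @return the trained \code{har_model} with a \code{history} element
#'   (data frame epoch/train_loss/val_loss) and \code{best_epoch}
#' @export
train_with_early_stopping <- function(model, windows, val_windows,
                                      epochs = 30, patience = 5,
                                      batch_size = 64, lr = 1e-3,
                                      seed = 1L, verbose = FALSE) {
  if (patience < 1) stop("patience must be at least 1")
  cls <- model$classes
  y_tr <- match(windows$label, cls)
  y_va <- match(val_windows$label, cls)
  if (anyNA(y_tr) || anyNA(y_va))
    stop("window labels outside the model's class set")
  x_tr <- windows$x; x_va <- val_windows$x
  flat <- .flat_params(model)
  state <- adam_init(flat)
  set.seed(seed)
  n <- nrow(x_tr)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best_loss <- Inf; best_flat <- flat; best_epoch <- 0L; bad <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (s in seq(1, n, by = batch_size)) {
      e <- min(n, s + batch_size - 1)
      ix <- ord[s:e]
      out <- model_forward(model, x_tr[ix, , drop = FALSE], y_tr[ix])
      if (!is.finite(out$loss))
        stop(sprintf("non-finite training loss at epoch %d; last batch size %d",
                     ep, length(ix)))
      st <- adam_step(flat, out$grads, state, lr = lr)
      flat <- st$params; state <- st$state
      model <- .unflat_params(model, flat)
      tot <- tot + out$loss * length(ix)
    }
    vl <- .batch_loss(model, x_va, y_va)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, tot / n, vl))
    if (vl < best_loss) {
      best_loss <- vl; best_flat <- flat; best_epoch <- ep; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  model <- .unflat_params(model, best_flat)
  model$history <- hist
  model$best_epoch <- best_epoch
  model
}

#' Confusion matrix with a fixed class order
#'
#' @param truth,pred character vectors
#' @param classes class order (default: sorted union)
#' @return square integer matrix, rows = truth, cols = predicted
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

#' Evaluate predictions: weighted F1 and balanced accuracy
#'
#' Weighted F1 is the support-weighted mean of per-class F1; balanced
#' accuracy is the unweighted mean of per-class recall over classes
#' present in the test set (absent classes are excluded with a warning).
#' Both are reported as percentages.
#'
#' @param truth,pred character label vectors
#' @param classes class order for the report
#' @param fold,seed optional provenance recorded in the report
#' @return an \code{eval_report}: list with \code{per_class} data frame
#'   (precision/recall/f1/support), \code{weighted_f1},
#'   \code{balanced_accuracy}, \code{confusion}, \code{fold}, \code{seed}
#' @export
evaluate_predictions <- function(truth, pred, classes = NULL, fold = NA,
                                 seed = NA) {
  if (length(truth) == 0) stop("empty test set")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  cm <- confusion_matrix(truth, pred, classes)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, NA)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- support > 0
  if (any(!present))
    warning("class(es) absent from the test set excluded from balanced accuracy: ",
            paste(classes[!present], collapse = ", "))
  weighted_f1 <- 100 * sum((support[present] / sum(support)) * f1[present])
  balanced_accuracy <- 100 * mean(rec[present])
  structure(list(per_class = data.frame(class = classes,
                                        precision = as.numeric(prec),
                                        recall = as.numeric(rec),
                                        f1 = as.numeric(f1),
                                        support = as.integer(support)),
                 weighted_f1 = weighted_f1,
                 balanced_accuracy = balanced_accuracy,
                 confusion = cm, fold = fold, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: weighted F1 %.2f, balanced accuracy %.2f (n = %d)\n",
              x$weighted_f1, x$balanced_accuracy, sum(x$per_class$support)))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Evaluate a model on test windows
#'
#' @param model a trained \code{har_model}
#' @param windows an \code{event_windows}
#' @param fold,seed provenance for the report
#' @return an \code{eval_report}
#' @export
evaluate_model <- function(model, windows, fold = NA, seed = NA) {
  if (nrow(windows$x) == 0) stop("empty test set")
  pred <- predict_windows(model, windows)$label
  evaluate_predictions(windows$label, pred, classes = model$classes,
                       fold = fold, seed = seed)
}

#' Write an eval report as JSON
#' @param report an \code{eval_report}
#' @param path output path
#' @return \code{path} invisibly
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(weighted_f1 = report$weighted_f1,
                            balanced_accuracy = report$balanced_accuracy,
                            per_class = report$per_class,
                            confusion = as.data.frame.matrix(as.matrix(report$confusion)),
                            fold = report$fold, seed = report$seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Full stratified-CV protocol
#'
#' 70/30 stratified outer split, then one model per inner fold (trained on
#' the other folds, early-stopped on the held-out fold), each evaluated on
#' the outer 30\% test set; reports are averaged.
#'
#' @param build_fn function(seed) returning a fresh \code{har_model}
#' @param windows an \code{event_windows}
#' @param folds inner folds (default 3)
#' @param seed RNG seed controlling split, init and batching
#' @param ... passed to \code{\link{train_with_early_stopping}}
#' @return list with \code{reports} (per fold), \code{mean_weighted_f1},
#'   \code{mean_balanced_accuracy}, \code{models}
#' @export
cross_validate <- function(build_fn, windows, folds = 3, seed = 1L, ...) {
  sp <- split_and_fold(windows$label, folds = folds, seed = seed)
  test_w <- windows[sp$test_idx]
  reports <- list(); models <- list()
  for (f in seq_len(folds)) {
    tr <- windows[sp$train_idx[sp$fold != f]]
    va <- windows[sp$train_idx[sp$fold == f]]
    m <- build_fn(seed + f)
    m <- train_with_early_stopping(m, tr, va, seed = seed + f, ...)
    reports[[f]] <- evaluate_model(m, test_w, fold = f, seed = seed)
    models[[f]] <- m
  }
  list(reports = reports,
       mean_weighted_f1 = mean(vapply(reports, `[[`, 0, "weighted_f1")),
       mean_balanced_accuracy = mean(vapply(reports, `[[`, 0, "balanced_accuracy")),
       models = models)
}
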