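# Window classifiers: embedding + 1-D U-Net (per-position segmenter whose
# positionwise probabilities are pooled into a window label) and the FCN and
# LSTM baselines. All three consume index-encoded EventWindows.

#' U-Net configuration
#'
#' Defaults follow the published architecture: encoder convolution filters
#' 64, 128, 256, 512, 1024 (the last is the bottleneck), decoder filters
#' 512, 256, 128, 64, kernel 3, max-pool 2, upsampling 2, and a
#' 64-dimensional token embedding. \code{depth_scale} multiplies the
#' filter counts so that desk-scale experiments train in seconds while
#' keeping the printed sizes as the default; the embedding width is the
#' input representation and is not scaled.
#'
#' @param embed_dim embedding width (default 64)
#' @param encoder_filters integer vector, last entry = bottleneck
#' @param decoder_filters integer vector, length = length(encoder_filters)-1
#' @param kernel odd convolution kernel size
#' @param pool max-pool width (must equal \code{upsample})
#' @param upsample upsampling factor
#' @param n_classes number of activity classes
#' @param depth_scale multiplier applied to all widths
#' @return an object of class \code{unet_config}
#' @export
unet_config <- function(embed_dim = 64,
                        encoder_filters = c(64, 128, 256, 512, 1024),
                        decoder_filters = c(512, 256, 128, 64),
                        kernel = 3, pool = 2, upsample = 2,
                        n_classes = 2, depth_scale = 1) {
  if (length(decoder_filters) != length(encoder_filters) - 1)
    stop("decoder_filters must have one entry fewer than encoder_filters")
  if (kernel %% 2 != 1) stop("kernel must be odd")
  if (pool != upsample) stop("pool and upsample factors must match")
  if (n_classes < 2) stop("need at least 2 classes")
  sc <- function(v) pmax(1L, as.integer(round(v * depth_scale)))
  # depth_scale shrinks the network's filter counts; the embedding is the
  # input representation and keeps its configured width
  structure(list(embed_dim = as.integer(embed_dim),
                 encoder_filters = sc(encoder_filters),
                 decoder_filters = sc(decoder_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 upsample = as.integer(upsample),
                 n_classes = as.integer(n_classes),
                 depth_scale = depth_scale),
            class = "unet_config")
}

#' Encoder feature lengths of the U-Net for a given input length
#'
#' The input is internally zero-padded (on the left, like the window
#' padding) up to the next multiple of \code{pool^n_pools}. Returns the
#' sequence-length at the input of each encoder stage including the
#' bottleneck; with the printed configuration and W = 64 this is
#' 64, 32, 16, 8, 4.
#'
#' @param cfg a \code{unet_config}
#' @param W window length
#' @return integer vector of length \code{length(encoder_filters)}
#' @export
unet_feature_lengths <- function(cfg, W) {
  n_pools <- length(cfg$encoder_filters) - 1
  Wp <- unet_internal_length(cfg, W)
  Wp %/% cfg$pool^(0:n_pools)
}

#' @rdname unet_feature_lengths
#' @export
unet_internal_length <- function(cfg, W) {
  div <- cfg$pool^(length(cfg$encoder_filters) - 1)
  as.integer(ceiling(W / div) * div)
}

.model_class <- function() c("har_model", "list")

#' Build the embedding + 1-D U-Net window classifier
#'
#' Encoder: repeated [conv(k) x2 + ReLU, maxpool] blocks with the
#' configured filter counts; bottleneck conv x2; decoder: repeated
#' [nearest-neighbour upsample, channel concatenation with the same-length
#' encoder feature (skip connection), conv x2]; head: per-position linear
#' projection + softmax. Output length equals input length. With
#' \code{embedding = FALSE} the input is the one-hot token encoding
#' instead of a learned embedding (the ablation variant).
#'
#' @param cfg a \code{unet_config}
#' @param W window length
#' @param vocab_size number of real tokens V (indices 1..V; V+1 = UNK)
#' @param classes character vector of class labels (prediction order)
#' @param embedding use a learned embedding (default TRUE)
#' @param seed RNG seed for weight initialization
#' @return a \code{har_model}
#' @export
build_unet <- function(cfg, W, vocab_size, classes, embedding = TRUE,
                       seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  if (W < cfg$pool) stop("window length too short for the pooling ladder; ",
                         "increase W or reduce the number of encoder stages")
  set.seed(seed)
  nf <- length(cfg$encoder_filters)
  n_pools <- nf - 1
  d_in <- if (embedding) cfg$embed_dim else vocab_size + 1L
  p <- list()
  if (embedding) p$emb <- embedding_init(vocab_size + 1L, cfg$embed_dim)
  c_prev <- d_in
  for (i in seq_len(n_pools)) {
    f <- cfg$encoder_filters[i]
    p[[sprintf("enc%da", i)]] <- conv1d_init(cfg$kernel, c_prev, f)
    p[[sprintf("enc%db", i)]] <- conv1d_init(cfg$kernel, f, f)
    c_prev <- f
  }
  fb <- cfg$encoder_filters[nf]
  p$bota <- conv1d_init(cfg$kernel, c_prev, fb)
  p$botb <- conv1d_init(cfg$kernel, fb, fb)
  c_prev <- fb
  for (j in seq_along(cfg$decoder_filters)) {
    f <- cfg$decoder_filters[j]
    skip_ch <- cfg$encoder_filters[n_pools - j + 1]
    p[[sprintf("dec%da", j)]] <- conv1d_init(cfg$kernel, skip_ch + c_prev, f)
    p[[sprintf("dec%db", j)]] <- conv1d_init(cfg$kernel, f, f)
    c_prev <- f
  }
  p$head <- conv1d_init(1L, c_prev, cfg$n_classes)
  structure(list(type = "unet", cfg = cfg, W = as.integer(W),
                 W_internal = unet_internal_length(cfg, W),
                 vocab_size = as.integer(vocab_size), classes = classes,
                 embedding = embedding, params = p, seed = seed),
            class = .model_class())
}

#' Build the FCN baseline
#'
#' Three 1-D convolution blocks — 128 filters kernel 8, 256 filters kernel
#' 5, 128 filters kernel 3 (stride 1, zero-padding 'same') — followed by
#' global average pooling over real (non-padding) positions and a softmax
#' window classifier. Filter counts scale with \code{depth_scale}.
#'
#' @param n_classes number of classes (>= 2)
#' @param vocab_size number of real tokens V
#' @param classes class label vector
#' @param embed_dim embedding width
#' @param embedding use a learned embedding; FALSE = one-hot input
#' @param depth_scale filter multiplier
#' @param seed RNG seed
#' @return a \code{har_model}
#' @export
build_fcn <- function(n_classes, vocab_size, classes, embed_dim = 64,
                      embedding = TRUE, depth_scale = 1, seed = 1L) {
  if (n_classes < 2) stop("need at least 2 classes")
  set.seed(seed)
  sc <- function(v) max(1L, as.integer(round(v * depth_scale)))
  d_in <- if (embedding) as.integer(embed_dim) else vocab_size + 1L
  spec <- list(c(sc(128), 8L), c(sc(256), 5L), c(sc(128), 3L))
  p <- list()
  if (embedding) p$emb <- embedding_init(vocab_size + 1L, d_in)
  c_prev <- d_in
  for (i in seq_along(spec)) {
    p[[sprintf("conv%d", i)]] <- conv1d_init(spec[[i]][2], c_prev, spec[[i]][1])
    c_prev <- spec[[i]][1]
  }
  p$out <- dense_init(c_prev, n_classes)
  structure(list(type = "fcn", cfg = list(n_classes = as.integer(n_classes),
                                          layer_spec = list(c(128L, 8L), c(256L, 5L), c(128L, 3L)),
                                          embed_dim_arg = embed_dim,
                                          depth_scale = depth_scale),
                 vocab_size = as.integer(vocab_size), classes = classes,
                 embedding = embedding, params = p, seed = seed),
            class = .model_class())
}

#' Build the LSTM baseline
#'
#' Embedding (64) -> LSTM (64 units) -> softmax classifier on the final
#' hidden state; padding positions are masked (the recurrent state is
#' carried through them unchanged). \code{embedding = FALSE} feeds one-hot
#' token vectors directly, the ablation variant.
#'
#' @param n_classes number of classes (>= 2)
#' @param vocab_size number of real tokens V
#' @param classes class label vector
#' @param units LSTM hidden units (default 64)
#' @param embed_dim embedding width (default 64)
#' @param embedding learned embedding vs one-hot input
#' @param depth_scale width multiplier
#' @param seed RNG seed
#' @return a \code{har_model}
#' @export
build_lstm <- function(n_classes, vocab_size, classes, units = 64,
                       embed_dim = 64, embedding = TRUE, depth_scale = 1,
                       seed = 1L) {
  if (n_classes < 2) stop("need at least 2 classes")
  set.seed(seed)
  sc <- function(v) max(1L, as.integer(round(v * depth_scale)))
  units <- sc(units)
  d_in <- if (embedding) as.integer(embed_dim) else vocab_size + 1L
  p <- list()
  if (embedding) p$emb <- embedding_init(vocab_size + 1L, d_in)
  p$lstm <- lstm_init(d_in, units)
  p$out <- dense_init(units, n_classes)
  structure(list(type = "lstm", cfg = list(n_classes = as.integer(n_classes),
                                           units = units, units_arg = units / depth_scale,
                                           embed_dim_arg = embed_dim,
                                           depth_scale = depth_scale),
                 vocab_size = as.integer(vocab_size), classes = classes,
                 embedding = embedding, params = p, seed = seed),
            class = .model_class())
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("har_model <%s>%s: %d classes, vocab %d, %d parameters\n",
              x$type, if (x$embedding) " + embedding" else " (one-hot)",
              length(x$classes), x$vocab_size, count_params(x)))
  invisible(x)
}

#' Total trainable parameter count
#' @param model a \code{har_model}
#' @return integer count
#' @export
count_params <- function(model) {
  n <- 0
  for (p in model$params) {
    if (is.list(p)) {
      for (nm in c("W", "b", "Wx", "Wh")) if (!is.null(p[[nm]])) n <- n + length(p[[nm]])
    } else n <- n + length(p)
  }
  n
}

# Flatten params into a named list of plain arrays for the optimizer, and
# scatter gradients back with matching names.
.flat_params <- function(model) {
  out <- list()
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    if (is.list(p)) {
      for (f in c("W", "b", "Wx", "Wh"))
        if (!is.null(p[[f]])) out[[paste0(nm, ".", f)]] <- p[[f]]
    } else out[[nm]] <- p
  }
  out
}

.unflat_params <- function(model, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) model$params[[parts[1]]][[parts[2]]] <- flat[[nm]]
    else model$params[[nm]] <- flat[[nm]]
  }
  model
}

# Left-pad an index matrix to the model's internal length (U-Net only).
.pad_idx <- function(idx, W_target) {
  if (ncol(idx) == W_target) return(idx)
  cbind(matrix(0L, nrow(idx), W_target - ncol(idx)), idx)
}

.input_forward <- function(model, idx) {
  if (model$embedding) {
    ef <- embedding_forward(model$params$emb, idx)
    list(x = ef$y, iv = ef$iv)
  } else {
    list(x = onehot_input(idx, model$vocab_size + 1L), iv = NULL)
  }
}

# ---------------------------------------------------------------------------
# Forward/backward per architecture. `target` is an integer class vector
# (1-based, aligned with model$classes); NULL for inference.
# Returns list(loss, probs (B x n_classes pooled), per_position (unet),
# grads (flat, when target given)).

model_forward <- function(model, idx, target = NULL) {
  switch(model$type,
         unet = .unet_fb(model, idx, target),
         fcn  = .fcn_fb(model, idx, target),
         lstm = .lstm_fb(model, idx, target),
         stop("unknown model type"))
}

.unet_fb <- function(model, idx, target) {
  cfg <- model$cfg
  idx <- .pad_idx(idx, model$W_internal)
  B <- nrow(idx); Wp <- ncol(idx)
  mask <- (idx > 0) * 1
  inp <- .input_forward(model, idx)
  x <- inp$x
  n_pools <- length(cfg$encoder_filters) - 1
  caches <- list()
  skips <- list()
  for (i in seq_len(n_pools)) {
    for (s in c("a", "b")) {
      nm <- sprintf("enc%d%s", i, s)
      cf <- conv1d_forward(model$params[[nm]], x)
      rf <- relu_forward(cf$y)
      caches[[nm]] <- list(conv = cf$cache, relu = rf$mask)
      x <- rf$y
    }
    skips[[i]] <- x
    mp <- maxpool2_forward(x)
    caches[[sprintf("pool%d", i)]] <- mp$cache
    x <- mp$y
  }
  for (s in c("a", "b")) {
    nm <- paste0("bot", s)
    cf <- conv1d_forward(model$params[[nm]], x)
    rf <- relu_forward(cf$y)
    caches[[nm]] <- list(conv = cf$cache, relu = rf$mask)
    x <- rf$y
  }
  for (j in seq_along(cfg$decoder_filters)) {
    x <- upsample2_forward(x)
    sk <- skips[[n_pools - j + 1]]
    cc <- concat_forward(sk, x)
    caches[[sprintf("cat%d", j)]] <- cc$c1
    x <- cc$y
    for (s in c("a", "b")) {
      nm <- sprintf("dec%d%s", j, s)
      cf <- conv1d_forward(model$params[[nm]], x)
      rf <- relu_forward(cf$y)
      caches[[nm]] <- list(conv = cf$cache, relu = rf$mask)
      x <- rf$y
    }
  }
  hf <- conv1d_forward(model$params$head, x)
  logits <- hf$y                                  # (B, Wp, nc)
  nc <- cfg$n_classes
  lm <- matrix(logits, B * Wp, nc)
  probs_pos <- softmax_rows(lm)                   # rows: (b, w) column-major
  # pooled probability: mean over non-padding positions
  wv <- as.vector(mask)
  pooled <- rowsum(probs_pos * wv, group = rep(seq_len(B), times = Wp)) /
    pmax(rowSums(matrix(wv, B, Wp)), 1)
  per_position <- array(probs_pos, c(B, Wp, nc))
  if (is.null(target))
    return(list(probs = pooled, per_position = per_position, mask = mask))
  # every real position inherits the window label; padding masked out
  tgt_pos <- rep(target, times = Wp)
  cl <- ce_loss_grad(probs_pos, tgt_pos, weight = wv)
  dlogits <- array(cl$dlogits, c(B, Wp, nc))
  g <- list()
  hb <- conv1d_backward(model$params$head, hf$cache, dlogits)
  g[["head.W"]] <- hb$dW; g[["head.b"]] <- hb$db
  dx <- hb$dx
  for (j in rev(seq_along(cfg$decoder_filters))) {
    for (s in c("b", "a")) {
      nm <- sprintf("dec%d%s", j, s)
      dx <- relu_backward(caches[[nm]]$relu, dx)
      cb <- conv1d_backward(model$params[[nm]], caches[[nm]]$conv, dx)
      g[[paste0(nm, ".W")]] <- cb$dW; g[[paste0(nm, ".b")]] <- cb$db
      dx <- cb$dx
    }
    sp <- concat_backward(dx, caches[[sprintf("cat%d", j)]])
    dskip <- sp$da
    dx <- upsample2_backward(sp$db)
    # stash the skip-connection gradient under its encoder stage index
    caches[[sprintf("dskip%d", n_pools - j + 1)]] <- dskip
  }
  for (s in c("b", "a")) {
    nm <- paste0("bot", s)
    dx <- relu_backward(caches[[nm]]$relu, dx)
    cb <- conv1d_backward(model$params[[nm]], caches[[nm]]$conv, dx)
    g[[paste0(nm, ".W")]] <- cb$dW; g[[paste0(nm, ".b")]] <- cb$db
    dx <- cb$dx
  }
  for (i in rev(seq_len(n_pools))) {
    dx <- maxpool2_backward(caches[[sprintf("pool%d", i)]], dx)
    dsk <- caches[[sprintf("dskip%d", i)]]
    if (!is.null(dsk)) dx <- dx + dsk
    for (s in c("b", "a")) {
      nm <- sprintf("enc%d%s", i, s)
      dx <- relu_backward(caches[[nm]]$relu, dx)
      cb <- conv1d_backward(model$params[[nm]], caches[[nm]]$conv, dx)
      g[[paste0(nm, ".W")]] <- cb$dW; g[[paste0(nm, ".b")]] <- cb$db
      dx <- cb$dx
    }
  }
  if (model$embedding)
    g[["emb"]] <- embedding_backward(model$params$emb, inp$iv, dx)
  list(loss = cl$loss, probs = pooled, per_position = per_position,
       mask = mask, grads = g)
}

.fcn_fb <- function(model, idx, target) {
  B <- nrow(idx); W <- ncol(idx)
  mask <- (idx > 0) * 1
  inp <- .input_forward(model, idx)
  x <- inp$x
  caches <- list()
  for (i in 1:3) {
    nm <- sprintf("conv%d", i)
    cf <- conv1d_forward(model$params[[nm]], x)
    rf <- relu_forward(cf$y)
    caches[[nm]] <- list(conv = cf$cache, relu = rf$mask)
    x <- rf$y
  }
  # masked global average pooling over positions
  C <- dim(x)[3]
  nreal <- pmax(rowSums(mask), 1)
  xm <- x * as.vector(mask)                    # mask recycles over channels
  pooled <- apply(xm, c(1, 3), sum) / nreal
  if (B == 1) pooled <- matrix(pooled, 1, C)
  logits <- dense_forward(model$params$out, pooled)
  probs <- softmax_rows(logits)
  if (is.null(target)) return(list(probs = probs))
  cl <- ce_loss_grad(probs, target)
  g <- list()
  db <- dense_backward(model$params$out, pooled, cl$dlogits)
  g[["out.W"]] <- db$dW; g[["out.b"]] <- db$db
  dpooled <- db$dx                              # (B, C)
  dx <- array(0, dim(x))
  for (t in seq_len(W)) dx[, t, ] <- dpooled * (mask[, t] / nreal)
  for (i in 3:1) {
    nm <- sprintf("conv%d", i)
    dx <- relu_backward(caches[[nm]]$relu, dx)
    cb <- conv1d_backward(model$params[[nm]], caches[[nm]]$conv, dx)
    g[[paste0(nm, ".W")]] <- cb$dW; g[[paste0(nm, ".b")]] <- cb$db
    dx <- cb$dx
  }
  if (model$embedding)
    g[["emb"]] <- embedding_backward(model$params$emb, inp$iv, dx)
  list(loss = cl$loss, probs = probs, grads = g)
}

.lstm_fb <- function(model, idx, target) {
  B <- nrow(idx)
  mask <- (idx > 0) * 1
  inp <- .input_forward(model, idx)
  lf <- lstm_forward(model$params$lstm, inp$x, mask)
  logits <- dense_forward(model$params$out, lf$h)
  probs <- softmax_rows(logits)
  if (is.null(target)) return(list(probs = probs))
  cl <- ce_loss_grad(probs, target)
  g <- list()
  db <- dense_backward(model$params$out, lf$h, cl$dlogits)
  g[["out.W"]] <- db$dW; g[["out.b"]] <- db$db
  lb <- lstm_backward(model$params$lstm, lf$caches, db$dx)
  g[["lstm.Wx"]] <- lb$dWx; g[["lstm.Wh"]] <- lb$dWh; g[["lstm.b"]] <- lb$db
  if (model$embedding)
    g[["emb"]] <- embedding_backward(model$params$emb, inp$iv, lb$dx)
  list(loss = cl$loss, probs = probs, grads = g)
}

#' Classify windows
#'
#' For the U-Net the window label is the class with the highest mean
#' per-position probability over non-padding positions; for FCN/LSTM it is
#' the softmax argmax. Ties break toward the lowest class index.
#'
#' @param model a \code{har_model}
#' @param windows an \code{event_windows} or an integer index matrix
#' @param batch_size forward-pass batch size
#' @return list with \code{label} (character), \code{probs} (n x n_classes
#'   matrix, columns in \code{model$classes} order)
#' @export
predict_windows <- function(model, windows, batch_size = 256) {
  x <- if (inherits(windows, "event_windows")) windows$x else windows
  if (any(x >= model$vocab_size + 2L))
    stop("window contains a token index beyond the embedding table; ",
         "encode with the vocabulary the model was trained on")
  n <- nrow(x)
  probs <- matrix(0, n, length(model$classes))
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    probs[s:e, ] <- model_forward(model, x[s:e, , drop = FALSE])$probs
  }
  lab <- model$classes[max.col(probs, ties.method = "first")]
  list(label = lab, probs = probs)
}

#' Classify one window
#'
#' @param model a \code{har_model}
#' @param window integer index vector (length = training W) or a 1-row
#'   \code{event_windows}
#' @return list with \code{window_label} and, for the U-Net,
#'   \code{per_position} probabilities
#' @export
predict_window <- function(model, window) {
  x <- if (inherits(window, "event_windows")) window$x else matrix(as.integer(window), 1)
  out <- model_forward(model, x)
  lab <- model$classes[which.max(out$probs[1, ])]
  res <- list(window_label = lab, probs = out$probs[1, ])
  if (!is.null(out$per_position)) res$per_position <- out$per_position[1, , ]
  res
}

#' Aggregate per-position probabilities into a window label
#'
#' Mean probability over non-padding positions, then argmax with ties
#' broken toward the lowest class index.
#'
#' @param per_position W x n_classes probability matrix
#' @param mask logical/0-1 vector of real positions (default all real)
#' @param classes optional class labels
#' @return the winning class index, or label if \code{classes} given
#' @export
pool_position_probs <- function(per_position, mask = NULL, classes = NULL) {
  if (is.null(mask)) mask <- rep(1, nrow(per_position))
  m <- colSums(per_position * mask) / max(sum(mask), 1)
  i <- which.max(m)
  if (is.null(classes)) i else classes[i]
}

#' Save / load a model checkpoint
#'
#' Single-file text checkpoint (JSON) with the config, classes and all
#' weights embedded.
#'
#' @param model a \code{har_model}
#' @param path file path
#' @return \code{path} invisibly (save); a \code{har_model} (load)
#' @export
save_checkpoint <- function(model, path) {
  flat <- .flat_params(model)
  ser <- list(type = model$type, W = model$W, W_internal = model$W_internal,
              vocab_size = model$vocab_size, classes = model$classes,
              embedding = model$embedding, seed = model$seed,
              cfg = unclass(model$cfg),
              param_dims = lapply(flat, function(p) dim(p) %||% length(p)),
              params = lapply(flat, as.vector))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- ser$cfg
  if (ser$type == "unet") class(cfg) <- "unet_config"
  skel <- switch(ser$type,
    unet = build_unet(cfg, ser$W, ser$vocab_size, ser$classes,
                      embedding = ser$embedding, seed = ser$seed),
    fcn = build_fcn(cfg$n_classes, ser$vocab_size, ser$classes,
                    embed_dim = cfg$embed_dim_arg %||% 64,
                    embedding = ser$embedding, depth_scale = cfg$depth_scale,
                    seed = ser$seed),
    lstm = build_lstm(cfg$n_classes, ser$vocab_size, ser$classes,
                      units = cfg$units_arg %||% cfg$units,
                      embed_dim = cfg$embed_dim_arg %||% 64,
                      embedding = ser$embedding,
                      depth_scale = cfg$depth_scale %||% 1,
                      seed = ser$seed))
  flat <- list()
  for (nm in names(ser$params)) {
    v <- as.numeric(ser$params[[nm]])
    d <- ser$param_dims[[nm]]
    if (length(d) > 1) dim(v) <- d
    flat[[nm]] <- v
  }
  .unflat_params(skel, flat)
}
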