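# NLP-style front end: tokenize events, build a frequency-index vocabulary,
# cut the encoded stream into fixed-size zero-padded sensor-event windows.

#' Tokenize sensor events
#'
#' A sensor event becomes the concatenation of its sensor id and value with
#' the timestamp dropped, e.g. \code{"M011ON"}. Numeric values (temperature
#' sensors) are discretized into fixed-width bins first, so \code{("T001",
#' "21.5")} with 5-degree bins becomes \code{"T001_B4"} (bin =
#' \code{floor(21.5 / 5)}).
#'
#' @param sensor_id character vector of sensor ids
#' @param value character vector of sensor values
#' @param numeric_bin_width bin width for numeric values (default 5)
#' @return character vector of tokens
#' @export
#' @examples
#' tokenize_event("M011", "ON")          # "M011ON"
#' tokenize_event("T001", "21.5")        # "T001_B4"
tokenize_event <- function(sensor_id, value, numeric_bin_width = 5) {
  stopifnot(all(nzchar(sensor_id)), all(nzchar(value)))
  num <- suppressWarnings(as.numeric(value))
  is_num <- !is.na(num)
  out <- paste0(sensor_id, value)
  if (any(is_num)) {
    bin <- floor(num[is_num] / numeric_bin_width)
    out[is_num] <- sprintf("%s_B%d", sensor_id[is_num], as.integer(bin))
  }
  out
}

#' Build a frequency-index vocabulary
#'
#' Tokens are assigned integer indices 1..V by descending frequency, ties
#' broken lexicographically. Index 0 is reserved for padding and index V+1
#' for the out-of-vocabulary token \code{"UNK"}. Built from the training
#' split only to avoid leakage.
#'
#' @param tokens character vector (a multiset) of training tokens
#' @return an object of class \code{habit_vocab}: list with \code{index}
#'   (named integer vector token -> index), \code{freq} (named counts),
#'   \code{size} (V), \code{unk_index} (V+1)
#' @export
build_vocabulary <- function(tokens) {
  if (length(tokens) == 0) stop("cannot build a vocabulary from zero tokens")
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  toks <- names(tab)[ord]
  idx <- seq_along(toks)
  names(idx) <- toks
  structure(list(index = idx,
                 freq = as.integer(tab)[ord],
                 size = length(toks),
                 unk_index = length(toks) + 1L),
            class = "habit_vocab")
}

#' @export
print.habit_vocab <- function(x, ...) {
  cat(sprintf("habit_vocab: %d tokens (+ pad 0, UNK %d)\n", x$size, x$unk_index))
  invisible(x)
}

#' Encode tokens as vocabulary indices
#'
#' @param vocab a \code{habit_vocab}
#' @param tokens character vector
#' @return integer indices in 1..V, with unseen tokens mapped to the UNK
#'   index V+1
#' @export
encode_tokens <- function(vocab, tokens) {
  i <- unname(vocab$index[tokens])
  i[is.na(i)] <- vocab$unk_index
  as.integer(i)
}

#' Decode vocabulary indices back to tokens
#'
#' @param vocab a \code{habit_vocab}
#' @param indices integer vector (0 = padding -> \code{"<pad>"},
#'   V+1 -> \code{"UNK"})
#' @return character vector
#' @export
decode_tokens <- function(vocab, indices) {
  toks <- c("<pad>", names(vocab$index), "UNK")
  toks[indices + 1L]
}

#' Write / read a vocabulary as a two-column text table
#'
#' @param vocab a \code{habit_vocab}
#' @param path file path
#' @return \code{path} invisibly (write); a \code{habit_vocab} (read)
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(data.frame(token = names(vocab$index),
                                index = unname(vocab$index)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  idx <- as.integer(df$index)
  names(idx) <- df$token
  structure(list(index = idx, freq = rep(NA_integer_, length(idx)),
                 size = length(idx), unk_index = length(idx) + 1L),
            class = "habit_vocab")
}

#' Segment an encoded event stream into sensor-event windows (SEW)
#'
#' One window ends at every \code{step}-th event and contains the \code{W}
#' most recent event indices, zero-padded on the left when fewer than
#' \code{W} events precede. The window label is the last event's label
#' (\code{label = "last"}) or the majority label over real events
#' (\code{label = "majority"}); the window's \code{end_timestamp} is the
#' last event's timestamp. With step 1 this yields one window per event —
#' recognition every time a new event fires.
#'
#' @param indices integer vector of encoded events (values >= 1)
#' @param labels character vector of per-event activity labels
#' @param W window size (>= 2); the study grid is 25/50/75/100
#' @param step window stride in events (default 1)
#' @param timestamps optional POSIXct vector of event times
#' @param label window-labeling rule, \code{"last"} or \code{"majority"}
#' @return an object of class \code{event_windows}: list with \code{x}
#'   (n_windows x W integer matrix, padding = 0), \code{label} (character),
#'   \code{end_timestamp} (POSIXct or NULL), \code{W}, \code{step}
#' @export
segment_windows <- function(indices, labels, W, step = 1L, timestamps = NULL,
                            label = c("last", "majority")) {
  label <- match.arg(label)
  if (W < 2) stop("window size W must be at least 2")
  if (step < 1) stop("step must be a positive integer")
  n <- length(indices)
  stopifnot(length(labels) == n)
  ends <- seq(from = min(step, n), to = n, by = step)
  if (n == 0) ends <- integer(0)
  # window count must be ceiling(n / step): ends at step, 2*step, ..., plus
  # a final partial-stride window is NOT taken -- ends only at multiples,
  # but ceiling(n/step) windows requires covering the tail event
  if (n > 0 && ends[length(ends)] != n) ends <- c(ends, n)
  m <- length(ends)
  x <- matrix(0L, nrow = m, ncol = W)
  lab <- character(m)
  for (j in seq_len(m)) {
    e <- ends[j]
    s <- max(1L, e - W + 1L)
    seg <- indices[s:e]
    x[j, (W - length(seg) + 1L):W] <- seg
    lab[j] <- if (label == "last") labels[e] else {
      t <- table(labels[s:e])
      names(t)[which.max(t)]   # majority, ties -> first alphabetically
    }
  }
  structure(list(x = x, label = lab,
                 end_timestamp = if (!is.null(timestamps)) timestamps[ends] else NULL,
                 W = as.integer(W), step = as.integer(step)),
            class = "event_windows")
}

#' @export
print.event_windows <- function(x, ...) {
  cat(sprintf("event_windows: %d windows of size %d (step %d), %d classes\n",
              nrow(x$x), x$W, x$step, length(unique(x$label))))
  invisible(x)
}

#' Subset windows
#' @param x an \code{event_windows}
#' @param i row index
#' @param ... unused
#' @export
`[.event_windows` <- function(x, i, ...) {
  structure(list(x = x$x[i, , drop = FALSE], label = x$label[i],
                 end_timestamp = if (!is.null(x$end_timestamp)) x$end_timestamp[i] else NULL,
                 W = x$W, step = x$step),
            class = "event_windows")
}

#' Full preprocessing: labeled events to encoded windows
#'
#' Tokenizes, encodes against \code{vocab} (building one from the whole
#' stream if NULL — pass a training-only vocabulary for honest evaluation),
#' and segments into windows.
#'
#' @param events a labeled \code{casas_events} (see \code{\link{label_events}})
#' @param W window size
#' @param step stride
#' @param vocab optional pre-built \code{habit_vocab}
#' @param numeric_bin_width forwarded to \code{\link{tokenize_event}}
#' @param include_other keep windows labeled "Other" (default TRUE)
#' @return list(windows = event_windows, vocab = habit_vocab)
#' @export
preprocess_events <- function(events, W, step = 1L, vocab = NULL,
                              numeric_bin_width = 5, include_other = TRUE) {
  toks <- tokenize_event(events$sensor_id, events$value, numeric_bin_width)
  if (is.null(vocab)) vocab <- build_vocabulary(toks)
  idx <- encode_tokens(vocab, toks)
  w <- segment_windows(idx, events$label, W, step, timestamps = events$timestamp)
  if (!include_other) w <- w[w$label != "Other"]
  list(windows = w, vocab = vocab)
}
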