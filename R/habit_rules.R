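# Habit mining: classified behavior sequences -> time-binned daily
# transactions -> FP-Growth frequent itemsets -> association rules ->
# timestamp-gap filtering -> precision against planted ground truth.
#
# Items are strings "Activity@HH" (activity plus the hour bin of its start
# time). Itemsets are kept canonically sorted; an itemset key joins its
# items with "\x1f".

.item_key <- function(items) paste(sort(items), collapse = "\x1f")
.key_items <- function(key) strsplit(key, "\x1f", fixed = TRUE)[[1]]

#' Make a time-binned item
#'
#' @param activity activity label
#' @param time POSIXct start time (or numeric hour)
#' @param bin_width_h bin width in hours (default 1)
#' @return character item like \code{"Eating@08"}
#' @export
behavior_item <- function(activity, time, bin_width_h = 1) {
  hr <- if (inherits(time, "POSIXt"))
    as.numeric(format(time, "%H", tz = "UTC")) +
      as.numeric(format(time, "%M", tz = "UTC")) / 60
  else as.numeric(time)
  bin <- floor(hr / bin_width_h) * bin_width_h
  sprintf("%s@%02d", activity, as.integer(bin))
}

#' Collapse classified windows into behavior instances
#'
#' Maximal runs of identical consecutive predicted labels become one
#' BehaviorInstance spanning the run (start/end = end-timestamps of the
#' first/last window of the run). Runs shorter than \code{min_run}
#' windows are discarded as classifier noise; runs labeled
#' \code{drop_label} are background, not behaviors, and are dropped too.
#' Adjacent same-label runs separated by a dropped run are not merged.
#'
#' @param labels character vector of predicted window labels, time-ordered
#' @param timestamps POSIXct end-timestamps of the windows
#' @param min_run minimum run length in windows (default 3)
#' @param drop_label background label excluded from behaviors
#' @param bin_width_h hour-bin width for the item time bin
#' @return data.frame(activity, start_time, end_time, time_bin, item)
#' @export
windows_to_behaviors <- function(labels, timestamps, min_run = 3,
                                 drop_label = "Other", bin_width_h = 1) {
  if (length(labels) == 0)
    return(data.frame(activity = character(0),
                      start_time = as.POSIXct(character(0), tz = "UTC"),
                      end_time = as.POSIXct(character(0), tz = "UTC"),
                      time_bin = integer(0), item = character(0)))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$lengths >= min_run & r$values != drop_label & !is.na(r$values)
  st <- timestamps[starts[keep]]
  en <- timestamps[ends[keep]]
  act <- r$values[keep]
  bin <- floor((as.numeric(format(st, "%H", tz = "UTC")) +
                  as.numeric(format(st, "%M", tz = "UTC")) / 60) / bin_width_h) *
    bin_width_h
  data.frame(activity = act, start_time = st, end_time = en,
             time_bin = as.integer(bin),
             item = sprintf("%s@%02d", act, as.integer(bin)),
             stringsAsFactors = FALSE)
}

#' Behavior instances from ground-truth annotations
#'
#' The true-label bypass: reads begin/end annotation pairs straight off a
#' \code{casas_events} stream, so the mining half can be exercised
#' independently of the classifier.
#'
#' @param events an annotated \code{casas_events}
#' @param bin_width_h hour-bin width
#' @return data.frame as in \code{\link{windows_to_behaviors}}
#' @export
behaviors_from_annotations <- function(events, bin_width_h = 1) {
  open <- list()
  rows <- list()
  for (i in seq_len(nrow(events))) {
    a <- events$activity[i]; b <- events$boundary[i]
    if (is.na(a)) next
    if (identical(b, "begin")) {
      open[[length(open) + 1]] <- list(activity = a, start = events$timestamp[i])
    } else if (identical(b, "end")) {
      pos <- Position(function(o) o$activity == a, open, right = TRUE)
      if (is.na(pos)) next
      rows[[length(rows) + 1]] <- data.frame(
        activity = a, start_time = open[[pos]]$start,
        end_time = events$timestamp[i], stringsAsFactors = FALSE)
      open[[pos]] <- NULL
    }
  }
  if (!length(rows))
    return(windows_to_behaviors(character(0), as.POSIXct(character(0), tz = "UTC")))
  df <- do.call(rbind, rows)
  df <- df[order(df$start_time), , drop = FALSE]
  bin <- floor((as.numeric(format(df$start_time, "%H", tz = "UTC")) +
                  as.numeric(format(df$start_time, "%M", tz = "UTC")) / 60) /
                 bin_width_h) * bin_width_h
  df$time_bin <- as.integer(bin)
  df$item <- sprintf("%s@%02d", df$activity, df$time_bin)
  rownames(df) <- NULL
  df
}

#' Build timestamped transactions from behavior instances
#'
#' Default scheme: one transaction per calendar day, containing each
#' behavior as the item (activity, hour bin) — matching daily-habit
#' semantics like "wake at 8, walk at 10". The alternative
#' \code{"ngram"} scheme slides a window of \code{k} consecutive
#' behaviors. Items are sets (duplicates within a transaction collapse).
#'
#' @param behaviors data.frame from \code{\link{windows_to_behaviors}} or
#'   \code{\link{behaviors_from_annotations}}, time-ordered
#' @param scheme \code{"daily"} or \code{"ngram"}
#' @param k behaviors per n-gram transaction (ngram scheme)
#' @return an object of class \code{habit_transactions}: list of
#'   transactions, each \code{list(id, items, instances)} where
#'   \code{instances} is the per-item first occurrence (item, start, end)
#' @export
build_transactions <- function(behaviors, scheme = c("daily", "ngram"), k = 5) {
  scheme <- match.arg(scheme)
  groups <- if (nrow(behaviors) == 0) list()
  else if (scheme == "daily") {
    day <- format(behaviors$start_time, "%Y-%m-%d", tz = "UTC")
    lapply(split(seq_len(nrow(behaviors)), day), identity)
  } else {
    n <- nrow(behaviors)
    if (n < k) list() else lapply(seq_len(n - k + 1), function(s) s:(s + k - 1))
  }
  tx <- lapply(seq_along(groups), function(g) {
    bi <- behaviors[groups[[g]], , drop = FALSE]
    # aggregate same-item instances: earliest start, latest end, so gap
    # anchors are the latest antecedent end / earliest consequent start
    # even when a behavior run is fragmented
    agg_start <- vapply(split(as.numeric(bi$start_time), bi$item), min, 0)
    agg_end <- vapply(split(as.numeric(bi$end_time), bi$item), max, 0)
    items <- sort(names(agg_start))
    list(id = if (scheme == "daily") names(groups)[g] else as.character(g),
         items = items,
         instances = data.frame(
           item = items,
           start = as.POSIXct(agg_start[items], origin = "1970-01-01", tz = "UTC"),
           end = as.POSIXct(agg_end[items], origin = "1970-01-01", tz = "UTC"),
           stringsAsFactors = FALSE))
  })
  structure(tx, class = "habit_transactions")
}

#' @export
print.habit_transactions <- function(x, ...) {
  cat(sprintf("habit_transactions: %d transactions, %d distinct items\n",
              length(x), length(unique(unlist(lapply(x, `[[`, "items"))))))
  invisible(x)
}

#' Write transactions as a basket file (one line per transaction,
#' comma-separated items)
#' @param tx a \code{habit_transactions}
#' @param path output path
#' @return \code{path} invisibly
#' @export
write_transactions <- function(tx, path) {
  writeLines(vapply(tx, function(t) paste(t$items, collapse = ","), ""), path)
  invisible(path)
}

.tx_items <- function(transactions) {
  if (inherits(transactions, "habit_transactions"))
    lapply(transactions, `[[`, "items")
  else transactions
}

#' Support and confidence of itemsets
#'
#' \code{itemset_support(Z, D)} is the fraction of transactions containing
#' every item of Z. \code{rule_confidence(X, Y, D)} is
#' \code{|T(X u Y)| / |T(X)|}; an error is signalled when no transaction
#' contains X.
#'
#' @param itemset,antecedent,consequent character vectors of items
#' @param transactions a \code{habit_transactions} or a list of character
#'   vectors
#' @return a fraction in [0, 1]
#' @export
itemset_support <- function(itemset, transactions) {
  D <- .tx_items(transactions)
  if (length(D) == 0) stop("empty transaction database")
  mean(vapply(D, function(t) all(itemset %in% t), TRUE))
}

#' @rdname itemset_support
#' @export
rule_confidence <- function(antecedent, consequent, transactions) {
  D <- .tx_items(transactions)
  if (length(D) == 0) stop("empty transaction database")
  nx <- sum(vapply(D, function(t) all(antecedent %in% t), TRUE))
  if (nx == 0) stop("antecedent occurs in no transaction; confidence undefined")
  nxy <- sum(vapply(D, function(t) all(c(antecedent, consequent) %in% t), TRUE))
  nxy / nx
}

# --- FP-Growth ---------------------------------------------------------------

.fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item; e$count <- 0; e$parent <- parent; e$children <- list()
  e
}

.fp_build <- function(trans, counts, item_order) {
  root <- .fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  for (i in seq_along(trans)) {
    items <- trans[[i]]
    items <- items[order(match(items, item_order))]
    node <- root
    for (it in items) {
      ch <- node$children[[it]]
      if (is.null(ch)) {
        ch <- .fp_node(it, node)
        node$children[[it]] <- ch
        header[[it]] <- c(header[[it]], ch)
      }
      ch$count <- ch$count + counts[i]
      node <- ch
    }
  }
  list(root = root, header = header)
}

.fp_mine <- function(trans, counts, min_count, suffix, out) {
  # item counts within this (conditional) database
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(trans))
    for (it in trans[[i]])
      tab[[it]] <- (tab[[it]] %||% 0) + counts[i]
  items <- ls(tab)
  cnt <- vapply(items, function(it) tab[[it]], 0)
  keep <- cnt >= min_count
  items <- items[keep]; cnt <- cnt[keep]
  if (length(items) == 0) return(invisible())
  ord <- order(-cnt, items)                 # descending frequency, lexicographic ties
  item_order <- items[ord]
  # prune infrequent items from transactions, then build the tree
  trans <- lapply(trans, function(t) t[t %in% item_order])
  tree <- .fp_build(trans, counts, item_order)
  for (it in rev(item_order)) {             # least frequent first
    supp_count <- tab[[it]]
    key <- .item_key(c(suffix, it))
    out[[key]] <- supp_count
    nodes <- tree$header[[it]]
    cpb <- list(); cpb_counts <- numeric(0)
    for (nd in nodes) {
      path <- character(0)
      p <- nd$parent
      while (!is.null(p) && !is.na(p$item)) { path <- c(p$item, path); p <- p$parent }
      if (length(path)) {
        cpb[[length(cpb) + 1]] <- path
        cpb_counts <- c(cpb_counts, nd$count)
      }
    }
    if (length(cpb))
      .fp_mine(cpb, cpb_counts, min_count, c(suffix, it), out)
  }
  invisible()
}

#' Mine frequent itemsets with FP-Growth
#'
#' Builds an FP-tree (items ordered by descending frequency within
#' transactions) and mines it recursively through conditional pattern
#' bases — no candidate generation. Returns exactly the itemsets whose
#' support is at least \code{min_support}, canonically ordered by support
#' descending, then lexicographically.
#'
#' @param transactions a \code{habit_transactions} or list of character
#'   vectors
#' @param min_support minimum support fraction in (0, 1]
#' @return data.frame with \code{items} (list column of sorted character
#'   vectors), \code{support} (fraction), \code{count}
#' @export
fp_growth <- function(transactions, min_support) {
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1)
    stop("min_support must be in (0, 1]")
  D <- .tx_items(transactions)
  if (length(D) == 0) stop("empty transaction database")
  n <- length(D)
  min_count <- min_support * n - 1e-9
  out <- new.env(parent = emptyenv())
  .fp_mine(D, rep(1, n), min_count, character(0), out)
  keys <- ls(out)
  if (length(keys) == 0)
    return(data.frame(items = I(list()), support = numeric(0), count = numeric(0)))
  count <- vapply(keys, function(k) out[[k]], 0)
  support <- count / n
  items <- lapply(keys, .key_items)
  sizes <- lengths(items)
  ord <- order(-support, sizes, keys)
  df <- data.frame(support = support[ord], count = count[ord])
  df$items <- items[ord]
  rownames(df) <- NULL
  df[, c("items", "support", "count")]
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset Z and every non-empty proper subset X of Z,
#' emits X -> Z \\ X when its confidence support(Z)/support(X) reaches
#' \code{min_confidence}. Anti-monotonicity guarantees every X is itself
#' in the frequent set.
#'
#' @param frequent data.frame from \code{\link{fp_growth}}
#' @param min_confidence minimum confidence fraction in [0, 1]
#' @return an \code{association_rules} data.frame: \code{antecedent},
#'   \code{consequent} (list columns), \code{support}, \code{confidence},
#'   canonically ordered (support desc, then lexicographic)
#' @export
generate_rules <- function(frequent, min_confidence) {
  supp <- stats::setNames(frequent$support,
                          vapply(frequent$items, .item_key, ""))
  ante <- list(); cons <- list(); rsupp <- numeric(0); rconf <- numeric(0)
  for (r in seq_len(nrow(frequent))) {
    z <- frequent$items[[r]]
    m <- length(z)
    if (m < 2) next
    sz <- frequent$support[r]
    for (bits in 1:(2^m - 2)) {
      sel <- bitwAnd(bits, 2^(seq_len(m) - 1)) > 0
      x <- z[sel]
      sx <- unname(supp[.item_key(x)])
      if (is.na(sx)) next   # cannot happen for a complete frequent set
      conf <- sz / sx
      if (conf >= min_confidence - 1e-12) {
        ante[[length(ante) + 1]] <- x
        cons[[length(cons) + 1]] <- z[!sel]
        rsupp <- c(rsupp, sz); rconf <- c(rconf, conf)
      }
    }
  }
  akeys <- vapply(ante, .item_key, "")
  ckeys <- vapply(cons, .item_key, "")
  ord <- order(-rsupp, akeys, ckeys)
  df <- data.frame(support = rsupp[ord], confidence = rconf[ord])
  df$antecedent <- ante[ord]
  df$consequent <- cons[ord]
  rownames(df) <- NULL
  df <- df[, c("antecedent", "consequent", "support", "confidence")]
  class(df) <- c("association_rules", "data.frame")
  df
}

#' Observed time gaps of rules
#'
#' For each rule and each supporting transaction, the gap is the signed
#' interval from the end of the latest antecedent behavior to the start of
#' the earliest consequent behavior (first instance per item). Adds
#' \code{median_gap_s} and \code{n_supporting} columns.
#'
#' @param rules an \code{association_rules}
#' @param transactions a \code{habit_transactions} (with instances)
#' @return \code{rules} with gap statistics, plus a \code{gaps} attribute
#'   (list of per-rule gap vectors, seconds)
#' @export
rule_gaps <- function(rules, transactions) {
  gaps <- vector("list", nrow(rules))
  med <- rep(NA_real_, nrow(rules))
  nsup <- integer(nrow(rules))
  for (r in seq_len(nrow(rules))) {
    x <- rules$antecedent[[r]]; y <- rules$consequent[[r]]
    gv <- numeric(0)
    for (t in transactions) {
      if (!all(c(x, y) %in% t$items)) next
      inst <- t$instances
      ant_end <- max(as.numeric(inst$end[inst$item %in% x]))
      con_start <- min(as.numeric(inst$start[inst$item %in% y]))
      gv <- c(gv, con_start - ant_end)
    }
    gaps[[r]] <- gv
    nsup[r] <- length(gv)
    if (length(gv)) med[r] <- stats::median(gv)
  }
  rules$median_gap_s <- med
  rules$n_supporting <- nsup
  attr(rules, "gaps") <- gaps
  rules
}

#' Temporal (timestamp-gap) habit filter
#'
#' A rule survives iff the magnitude of its median observed gap is at most
#' \code{max_gap_s}: behaviors that co-occur frequently but hours apart
#' are frequent itemsets, not habits. Rules with no supporting occurrence
#' are dropped with a warning. The surviving rules are the habit set.
#'
#' @param rules an \code{association_rules} (gap columns added if absent)
#' @param transactions a \code{habit_transactions}
#' @param max_gap_s gap threshold in seconds (default 1800 = 30 min;
#'   \code{Inf} keeps everything)
#' @return list(habits, removed): both \code{association_rules} with
#'   \code{median_gap_s}; \code{habits$kept} is TRUE
#' @export
temporal_filter <- function(rules, transactions, max_gap_s = 1800) {
  if (max_gap_s <= 0) stop("max_gap_s must be positive")
  if (is.null(rules$median_gap_s)) rules <- rule_gaps(rules, transactions)
  nosup <- rules$n_supporting == 0
  if (any(nosup))
    warning(sprintf("%d rule(s) had no supporting occurrences and were dropped",
                    sum(nosup)))
  keep <- !nosup & abs(rules$median_gap_s) <= max_gap_s
  habits <- rules[keep, , drop = FALSE]
  removed <- rules[!keep, , drop = FALSE]
  habits$kept <- if (nrow(habits)) TRUE else logical(0)
  removed$kept <- if (nrow(removed)) FALSE else logical(0)
  rownames(habits) <- rownames(removed) <- NULL
  list(habits = habits, removed = removed)
}

#' Score mined habits against planted ground truth
#'
#' A mined rule is a true positive iff its antecedent and consequent
#' itemsets exactly equal a planted habit's and the magnitude of its
#' median gap is within the planted tolerance. Precision = TP / (TP + FP);
#' undefined (NA, with a message) for an empty rule set.
#'
#' @param rules an \code{association_rules} with \code{median_gap_s}
#' @param ground_truth data.frame with \code{antecedent}, \code{consequent}
#'   (item strings), \code{gap_tol_s}
#' @return list(TP, FP, precision, matched): \code{matched} flags which
#'   planted habits were recovered
#' @export
evaluate_rules <- function(rules, ground_truth) {
  if (nrow(rules) == 0) {
    message("empty rule set; precision undefined")
    return(list(TP = 0L, FP = 0L, precision = NA_real_,
                matched = rep(FALSE, nrow(ground_truth))))
  }
  akeys <- vapply(rules$antecedent, .item_key, "")
  ckeys <- vapply(rules$consequent, .item_key, "")
  gt_a <- vapply(strsplit(ground_truth$antecedent, ",", fixed = TRUE), .item_key, "")
  gt_c <- vapply(strsplit(ground_truth$consequent, ",", fixed = TRUE), .item_key, "")
  is_tp <- logical(nrow(rules))
  matched <- rep(FALSE, nrow(ground_truth))
  for (r in seq_len(nrow(rules))) {
    hit <- which(gt_a == akeys[r] & gt_c == ckeys[r])
    if (length(hit) && !is.na(rules$median_gap_s[r]) &&
        abs(rules$median_gap_s[r]) <= ground_truth$gap_tol_s[hit[1]]) {
      is_tp[r] <- TRUE
      matched[hit[1]] <- TRUE
    }
  }
  tp <- sum(is_tp); fp <- nrow(rules) - tp
  list(TP = as.integer(tp), FP = as.integer(fp),
       precision = tp / (tp + fp), matched = matched)
}

#' Write a habit set as TSV
#'
#' Columns: antecedent, consequent (comma-joined items), support,
#' confidence, median gap (seconds), kept flag.
#'
#' @param habits,removed \code{association_rules} from
#'   \code{\link{temporal_filter}}
#' @param path output path
#' @return \code{path} invisibly
#' @export
write_habits <- function(habits, path, removed = NULL) {
  df <- rbind(habits, removed)
  flat <- data.frame(
    antecedent = vapply(df$antecedent, function(x) paste(sort(x), collapse = ","), ""),
    consequent = vapply(df$consequent, function(x) paste(sort(x), collapse = ","), ""),
    support = sprintf("%.6f", df$support),
    confidence = sprintf("%.6f", df$confidence),
    median_gap_s = sprintf("%.3f", df$median_gap_s),
    kept = df$kept)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Brute-force frequent itemsets and rules (reference oracle)
#'
#' Exhaustive enumeration of the itemset lattice, used as an independent
#' cross-check of the FP-Growth path in tests. Exponential in the number
#' of distinct items — small inputs only.
#'
#' @param transactions list of character vectors or \code{habit_transactions}
#' @param min_support minimum support fraction
#' @return data.frame like \code{\link{fp_growth}}
#' @export
apriori_bruteforce <- function(transactions, min_support) {
  D <- .tx_items(transactions)
  if (length(D) == 0) stop("empty transaction database")
  univ <- sort(unique(unlist(D)))
  m <- length(univ)
  if (m > 20) stop("too many distinct items for brute force")
  n <- length(D)
  # transaction-by-item membership matrix; support of S is the fraction of
  # rows containing all of S
  M <- t(vapply(D, function(t) univ %in% t, logical(m)))
  if (m == 1) M <- matrix(M, ncol = 1)
  keys <- character(0); supp <- numeric(0); items <- list()
  for (bits in seq_len(2^m - 1)) {
    sel <- bitwAnd(bits, 2^(seq_len(m) - 1)) > 0
    z <- univ[sel]
    s <- mean(rowSums(M[, sel, drop = FALSE]) == sum(sel))
    if (s >= min_support - 1e-9 / n) {
      keys <- c(keys, .item_key(z)); supp <- c(supp, s)
      items[[length(items) + 1]] <- z
    }
  }
  sizes <- lengths(items)
  ord <- order(-supp, sizes, keys)
  df <- data.frame(support = supp[ord], count = supp[ord] * n)
  df$items <- items[ord]
  rownames(df) <- NULL
  df[, c("items", "support", "count")]
}
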