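# Timestamps are handled in UTC throughout; CASAS logs carry no zone.
.TS_TZ <- "UTC"

#' Parse a CASAS-dialect timestamp
#'
#' @param x character vector "YYYY-MM-DD HH:MM:SS[.ffffff]"
#' @return POSIXct (UTC); NA where unparseable
#' @keywords internal
parse_casas_time <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = .TS_TZ))
  # strptime accepts some garbage ("2010-13-40") as NA already; also reject
  # strings without a full date-time shape
  bad <- !grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}(\\.\\d+)?$", x)
  out[bad] <- NA
  out
}

#' Format timestamps the way CASAS logs print them
#'
#' Microseconds are written explicitly (rounded, not truncated) so that a
#' write/read cycle reproduces the parsed time exactly.
#'
#' @param t POSIXct vector
#' @return character vector "YYYY-MM-DD HH:MM:SS.ffffff"
#' @keywords internal
format_casas_time <- function(t) {
  secs <- as.numeric(t)
  us <- round(secs * 1e6)
  whole <- floor(us / 1e6)
  frac <- us - whole * 1e6
  base <- format(as.POSIXct(whole, origin = "1970-01-01", tz = .TS_TZ),
                 "%Y-%m-%d %H:%M:%S", tz = .TS_TZ)
  sprintf("%s.%06d", base, as.integer(frac))
}

.new_casas_events <- function(timestamp, sensor_id, value, activity, boundary,
                              skipped = 0L, reordered = FALSE) {
  df <- data.frame(timestamp = timestamp, sensor_id = sensor_id, value = value,
                   activity = activity, boundary = boundary,
                   stringsAsFactors = FALSE)
  attr(df, "skipped_lines") <- skipped
  attr(df, "reordered") <- reordered
  class(df) <- c("casas_events", "data.frame")
  df
}

#' Read a CASAS-dialect ambient-sensor event log
#'
#' Each non-blank, non-comment line holds whitespace-separated fields:
#' date, time, sensor id, value, and optionally an activity annotation as
#' either two trailing fields ("Sleeping begin") or one fused field
#' ("Sleeping=begin"). Lines with an unparseable timestamp or fewer than
#' four fields are skipped with a warning and counted in the
#' \code{skipped_lines} attribute. Events are stable-sorted by timestamp;
#' if any reordering was needed a warning is raised and the
#' \code{reordered} attribute set.
#'
#' @param path path to the log file
#' @param sort_events stable-sort by timestamp after parsing (default TRUE)
#' @return a \code{casas_events} data frame with columns \code{timestamp}
#'   (POSIXct, UTC), \code{sensor_id}, \code{value}, \code{activity},
#'   \code{boundary} (the last two NA on unannotated events)
#' @export
#' @examples
#' f <- tempfile()
#' writeLines("2010-11-04 00:03:50.209589 M003 ON Sleeping begin", f)
#' read_events(f)
read_events <- function(path, sort_events = TRUE) {
  if (!file.exists(path)) stop("cannot read event log: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  n <- length(lines)
  ts_chr <- character(n); sid <- character(n); val <- character(n)
  act <- rep(NA_character_, n); bnd <- rep(NA_character_, n)
  keep <- logical(n)
  skipped <- 0L
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 4) { skipped <- skipped + 1L; next }
    ts_chr[i] <- paste(f[1], f[2])
    sid[i] <- f[3]; val[i] <- f[4]
    if (length(f) >= 6) {
      act[i] <- f[5]; bnd[i] <- f[6]
    } else if (length(f) == 5) {
      # fused "Activity=begin" dialect
      if (grepl("=", f[5], fixed = TRUE)) {
        parts <- strsplit(f[5], "=", fixed = TRUE)[[1]]
        act[i] <- parts[1]; bnd[i] <- parts[2]
      } else {
        act[i] <- f[5]   # annotation with missing boundary token
      }
    }
    keep[i] <- TRUE
  }
  ts <- parse_casas_time(ts_chr[keep])
  bad_ts <- is.na(ts)
  if (any(bad_ts)) skipped <- skipped + sum(bad_ts)
  if (skipped > 0)
    warning(sprintf("skipped %d malformed line(s) in %s", skipped, path))
  ok <- which(keep)[!bad_ts]
  ts <- ts[!bad_ts]
  bnd_ok <- bnd[ok]
  bnd_ok[!is.na(bnd_ok)] <- sub("[^a-zA-Z].*$", "", bnd_ok[!is.na(bnd_ok)])
  reordered <- FALSE
  ord <- seq_along(ts)
  if (sort_events && is.unsorted(ts)) {
    ord <- order(ts)            # order() is a stable sort for a single key
    reordered <- TRUE
    warning("events were out of chronological order; stable-sorted by timestamp")
  }
  .new_casas_events(ts[ord], sid[ok][ord], val[ok][ord],
                    act[ok][ord], bnd_ok[ord],
                    skipped = skipped, reordered = reordered)
}

#' Write events back out in the CASAS dialect
#'
#' Round-trips with \code{\link{read_events}} field-for-field, including
#' microsecond timestamps.
#'
#' @param events a \code{casas_events} data frame
#' @param path output path
#' @param header optional comment line(s) written with a leading "#"
#' @return \code{path}, invisibly
#' @export
write_events <- function(events, path, header = NULL) {
  stopifnot(is.data.frame(events))
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  if (nrow(events) > 0) {
    body <- paste(format_casas_time(events$timestamp),
                  events$sensor_id, events$value)
    ann <- !is.na(events$activity)
    body[ann] <- paste(body[ann], events$activity[ann], events$boundary[ann])
    lines <- c(lines, body)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write event log: ", path)
  invisible(path)
}

#' Assign an activity label to every event
#'
#' Events between a "begin" annotation and its matching "end" (both
#' inclusive) carry that activity; events outside every annotated interval
#' carry the reserved label \code{"Other"}. When intervals overlap, the
#' innermost (most recently begun) one wins. An "end" without a matching
#' open "begin" is ignored with a warning; a "begin" left open at
#' end-of-file is auto-closed at the last event with a warning.
#'
#' @param events a \code{casas_events} data frame, time-ordered
#' @param other_label label for events outside all intervals
#' @return \code{events} with an added \code{label} column
#' @export
label_events <- function(events, other_label = "Other") {
  n <- nrow(events)
  label <- character(n)
  if (n == 0) {
    events$label <- character(0)
    return(events)
  }
  open <- character(0)    # stack of open activities, most recent last
  for (i in seq_len(n)) {
    a <- events$activity[i]; b <- events$boundary[i]
    if (!is.na(a) && identical(b, "begin")) open <- c(open, a)
    label[i] <- if (length(open)) open[length(open)] else other_label
    if (!is.na(a) && identical(b, "end")) {
      pos <- which(open == a)
      if (length(pos) == 0) {
        warning(sprintf("'end' for %s with no open 'begin'; ignored", a))
      } else {
        open <- open[-pos[length(pos)]]   # close the innermost matching begin
      }
    }
  }
  if (length(open))
    warning(sprintf("unclosed 'begin' for %s at end of stream; auto-closed",
                    paste(unique(open), collapse = ", ")))
  events$label <- label
  events
}
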