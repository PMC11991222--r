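# Deterministic single-resident smart-home simulator. Emits CASAS-dialect
# event logs with begin/end activity annotations, planted short-gap habits,
# frequent-but-long-gap decoy pairs, ambient temperature readings and
# spurious noise events, plus per-event ground-truth labels.

#' Define a synthetic smart-home scenario
#'
#' Activities fire ON/OFF (or OPEN/CLOSE) event pairs from their sensor
#' set at a fixed rate for a log-normally distributed duration. Slots
#' place one activity occurrence per day either at a jittered clock time
#' or — for planted habits — a truncated-normal gap after another slot
#' ends, with an adherence probability. Ambient temperature readings and
#' spurious sensor events are emitted only outside annotated intervals,
#' so every event's true label is unambiguous.
#'
#' @param sensors data.frame with \code{id} (e.g. "M001"), \code{type}
#'   ("motion", "door", "temperature")
#' @param activities named list: label -> list(sensors, rate (events/min),
#'   dur_mean_min, dur_sdlog)
#' @param slots list of slots; each is list(id, activity, start = "HH:MM",
#'   jitter_sd_min) or list(id, activity, after = slot id, gap_mean_min,
#'   gap_sd_min, adherence)
#' @param decoys list of c(antecedent slot id, consequent slot id) pairs
#' @param noise_rate spurious events as a fraction of activity events
#' @param ambient_per_day target ambient temperature readings per day
#'   (emitted when a temperature sensor exists)
#' @param n_days days to simulate
#' @param start_date first day ("YYYY-MM-DD")
#' @param gap_tol_s gap tolerance recorded for planted habits (seconds)
#' @param seed RNG seed
#' @return an object of class \code{home_spec}
#' @export
home_spec <- function(sensors, activities, slots, decoys = list(),
                      noise_rate = 0.02, ambient_per_day = 24, n_days = 30,
                      start_date = "2024-03-01", gap_tol_s = 900, seed = 1L) {
  stopifnot(!anyDuplicated(sensors$id), n_days >= 1)
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]")
  slot_ids <- vapply(slots, `[[`, "", "id")
  if (anyDuplicated(slot_ids)) stop("duplicate slot ids")
  for (s in slots) {
    if (!s$activity %in% names(activities))
      stop("slot references undefined activity: ", s$activity)
    if (!is.null(s$after) && !s$after %in% slot_ids)
      stop("slot 'after' references unknown slot: ", s$after)
    if (!is.null(s$adherence) && (s$adherence < 0 || s$adherence > 1))
      stop("adherence must be in [0, 1]")
  }
  for (a in activities) if (a$rate <= 0) stop("activity firing rate must be positive")
  structure(list(sensors = sensors, activities = activities, slots = slots,
                 decoys = decoys, noise_rate = noise_rate,
                 ambient_per_day = ambient_per_day, n_days = as.integer(n_days),
                 start_date = start_date, gap_tol_s = gap_tol_s,
                 seed = as.integer(seed)),
            class = "home_spec")
}

.hhmm_to_s <- function(x) {
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  (p[1] * 60 + p[2]) * 60
}

# Nominal (no-jitter) start/end seconds-of-day per slot, used to derive the
# ground-truth item bins for planted habits and decoys.
.slot_nominal <- function(spec) {
  out <- list()
  for (s in spec$slots) {
    dur <- spec$activities[[s$activity]]$dur_mean_min * 60
    st <- if (!is.null(s$start)) .hhmm_to_s(s$start)
    else out[[s$after]]$end + s$gap_mean_min * 60
    out[[s$id]] <- list(start = st, end = st + dur, activity = s$activity,
                        bin = floor(st / 3600))
  }
  out
}

#' Ground-truth habit and decoy tables for a scenario
#'
#' @param spec a \code{home_spec}
#' @return list(habits, decoys): data.frames with \code{antecedent},
#'   \code{consequent} (item strings "Activity@HH"), \code{gap_tol_s}
#' @export
planted_truth <- function(spec) {
  nom <- .slot_nominal(spec)
  item_of <- function(id) sprintf("%s@%02d", nom[[id]]$activity, nom[[id]]$bin)
  hab <- list()
  for (s in spec$slots) if (!is.null(s$after))
    hab[[length(hab) + 1]] <- data.frame(
      antecedent = item_of(s$after), consequent = item_of(s$id),
      gap_tol_s = spec$gap_tol_s, stringsAsFactors = FALSE)
  habits <- if (length(hab)) do.call(rbind, hab)
  else data.frame(antecedent = character(0), consequent = character(0),
                  gap_tol_s = numeric(0))
  dec <- list()
  for (d in spec$decoys)
    dec[[length(dec) + 1]] <- data.frame(
      antecedent = item_of(d[1]), consequent = item_of(d[2]),
      stringsAsFactors = FALSE)
  decoys <- if (length(dec)) do.call(rbind, dec)
  else data.frame(antecedent = character(0), consequent = character(0))
  list(habits = habits, decoys = decoys)
}

.sensor_values <- function(type) {
  switch(type, motion = c("ON", "OFF"), door = c("OPEN", "CLOSE"),
         c("ON", "OFF"))
}

#' Simulate the home: CASAS-format events plus ground truth
#'
#' All randomness flows from \code{spec$seed}; identical specs give
#' byte-identical logs. Per occurrence the event-pair count is
#' deterministic, \code{round(rate * duration / 2)}; only the timing,
#' sensor choice and jitters are random. Overlapping slots are resolved
#' by queueing (the later slot waits) with a warning.
#'
#' @param spec a \code{home_spec}
#' @return list(events = \code{casas_events} with a \code{true_label}
#'   column, truth = list(habits, decoys, labels), spec)
#' @export
generate_home <- function(spec) {
  stopifnot(inherits(spec, "home_spec"))
  set.seed(spec$seed)
  day0 <- as.numeric(as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC"))
  stype <- stats::setNames(spec$sensors$type, spec$sensors$id)
  temp_sensors <- spec$sensors$id[spec$sensors$type == "temperature"]
  binary_sensors <- spec$sensors$id[spec$sensors$type != "temperature"]
  queued <- FALSE
  rows <- list()
  for (d in seq_len(spec$n_days)) {
    base <- day0 + (d - 1) * 86400
    # --- resolve slot times
    occ <- list()
    for (s in spec$slots) {
      act <- spec$activities[[s$activity]]
      dur <- stats::rlnorm(1, log(act$dur_mean_min * 60), act$dur_sdlog)
      if (!is.null(s$start)) {
        st <- base + .hhmm_to_s(s$start) + stats::rnorm(1, 0, s$jitter_sd_min * 60)
      } else {
        ant <- occ[[s$after]]
        if (is.null(ant)) next
        if (stats::runif(1) > (s$adherence %||% 1)) next
        gap <- max(30, stats::rnorm(1, s$gap_mean_min * 60, s$gap_sd_min * 60))
        st <- ant$end + gap
      }
      occ[[s$id]] <- list(start = st, end = st + dur, activity = s$activity)
    }
    if (length(occ) == 0) next
    # --- queue overlapping occurrences
    ord <- order(vapply(occ, `[[`, 0, "start"))
    occ <- occ[ord]
    for (i in seq_along(occ)[-1]) {
      if (occ[[i]]$start < occ[[i - 1]]$end + 10) {
        sh <- occ[[i - 1]]$end + 10 - occ[[i]]$start
        occ[[i]]$start <- occ[[i]]$start + sh
        occ[[i]]$end <- occ[[i]]$end + sh
        queued <- TRUE
      }
    }
    iv <- cbind(vapply(occ, `[[`, 0, "start"), vapply(occ, `[[`, 0, "end"))
    # --- activity events
    n_act_events <- 0L
    for (o in occ) {
      act <- spec$activities[[o$activity]]
      dur_s <- o$end - o$start
      n_pairs <- max(1, round(act$rate * (dur_s / 60) / 2))
      ons <- sort(o$start + stats::runif(n_pairs) * max(dur_s - 30, 1))
      ons[1] <- o$start
      offs <- pmin(ons + stats::runif(n_pairs, 5, 25), o$end)
      offs[n_pairs] <- o$end
      sens <- sample(act$sensors, n_pairs, replace = TRUE)
      vals <- vapply(sens, function(sid) .sensor_values(stype[[sid]])[1], "")
      vals_off <- vapply(sens, function(sid) .sensor_values(stype[[sid]])[2], "")
      df <- data.frame(t = c(ons, offs), sid = c(sens, sens),
                       val = c(vals, vals_off),
                       act = NA_character_, bnd = NA_character_,
                       true_label = o$activity, stringsAsFactors = FALSE)
      df <- df[order(df$t), , drop = FALSE]
      df$act[1] <- o$activity; df$bnd[1] <- "begin"
      df$act[nrow(df)] <- o$activity; df$bnd[nrow(df)] <- "end"
      n_act_events <- n_act_events + nrow(df)
      rows[[length(rows) + 1]] <- df
    }
    outside <- function(t) all(t < iv[, 1] | t > iv[, 2])
    # --- ambient temperature readings (outside annotated intervals)
    if (length(temp_sensors) && spec$ambient_per_day > 0) {
      hours <- seq(0, 23, length.out = spec$ambient_per_day)
      for (h in hours) {
        t <- base + h * 3600 + stats::runif(1) * 3600
        if (!outside(t)) next
        v <- sprintf("%.1f", 20 + 3 * sin(2 * pi * (h - 10) / 24) +
                       stats::rnorm(1, 0, 0.3))
        rows[[length(rows) + 1]] <- data.frame(
          t = t, sid = temp_sensors[1], val = v, act = NA_character_,
          bnd = NA_character_, true_label = "Other", stringsAsFactors = FALSE)
      }
    }
    # --- spurious noise events (outside annotated intervals)
    n_noise <- round(spec$noise_rate * n_act_events)
    for (k in seq_len(n_noise)) {
      for (try in 1:50) {
        t <- base + stats::runif(1) * 86400
        if (outside(t)) break
        t <- NA
      }
      if (is.na(t)) next
      sid <- sample(binary_sensors, 1)
      val <- sample(.sensor_values(stype[[sid]]), 1)
      rows[[length(rows) + 1]] <- data.frame(
        t = t, sid = sid, val = val, act = NA_character_,
        bnd = NA_character_, true_label = "Other", stringsAsFactors = FALSE)
    }
  }
  if (queued) warning("overlapping scheduled activities resolved by queueing")
  df <- do.call(rbind, rows)
  df <- df[order(df$t), , drop = FALSE]
  ev <- .new_casas_events(as.POSIXct(df$t, origin = "1970-01-01", tz = "UTC"),
                          df$sid, df$val, df$act, df$bnd)
  ev$true_label <- df$true_label
  truth <- planted_truth(spec)
  truth$labels <- df$true_label
  list(events = ev, truth = truth, spec = spec)
}

#' The default study scenario
#'
#' Five activities of daily living (Sleeping, Toileting, MealPrep, Eating,
#' Relaxing) over eight sensors and 60 days, with three planted short-gap
#' habits (wake -> toilet, meal preparation -> eating, relaxing ->
#' toilet), two frequent-but-long-gap decoy pairs, hourly ambient
#' temperature readings and 2\% spurious noise. Sized so the full
#' pipeline runs in minutes on one CPU.
#'
#' @param n_days days to simulate (default 60)
#' @param seed RNG seed (default 42)
#' @return a \code{home_spec}
#' @export
default_scenario <- function(n_days = 60, seed = 42L) {
  sensors <- data.frame(
    id = c("M001", "M002", "M003", "M004", "M005", "D001", "D002", "T001"),
    type = c("motion", "motion", "motion", "motion", "motion",
             "door", "door", "temperature"),
    stringsAsFactors = FALSE)
  activities <- list(
    Sleeping  = list(sensors = "M001", rate = 0.1, dur_mean_min = 360, dur_sdlog = 0.02),
    Toileting = list(sensors = c("M002", "D001"), rate = 4, dur_mean_min = 5, dur_sdlog = 0.05),
    MealPrep  = list(sensors = c("M003", "D002"), rate = 2, dur_mean_min = 20, dur_sdlog = 0.04),
    Eating    = list(sensors = "M004", rate = 1.6, dur_mean_min = 20, dur_sdlog = 0.04),
    Relaxing  = list(sensors = "M005", rate = 1, dur_mean_min = 45, dur_sdlog = 0.04))
  slots <- list(
    list(id = "sleep", activity = "Sleeping", start = "00:30", jitter_sd_min = 5),
    list(id = "toilet_am", activity = "Toileting", after = "sleep",
         gap_mean_min = 5, gap_sd_min = 1, adherence = 0.95),
    list(id = "mealprep", activity = "MealPrep", start = "07:15", jitter_sd_min = 5),
    list(id = "eat", activity = "Eating", after = "mealprep",
         gap_mean_min = 4, gap_sd_min = 1, adherence = 0.95),
    list(id = "relax", activity = "Relaxing", start = "10:20", jitter_sd_min = 4),
    list(id = "toilet_noon", activity = "Toileting", after = "relax",
         gap_mean_min = 6, gap_sd_min = 1.5, adherence = 0.95))
  decoys <- list(c("sleep", "relax"), c("toilet_am", "eat"))
  home_spec(sensors, activities, slots, decoys = decoys, noise_rate = 0.02,
            ambient_per_day = 24, n_days = n_days, gap_tol_s = 900,
            seed = seed)
}

#' Write a generated scenario to disk
#'
#' The log goes out in the CASAS dialect (with the seed in a header
#' comment); ground truth as JSON beside it; the spec as YAML.
#'
#' @param sim result of \code{\link{generate_home}}
#' @param log_path path for the event log
#' @return \code{log_path} invisibly
#' @export
write_home <- function(sim, log_path) {
  write_events(sim$events, log_path,
               header = sprintf("synthetic smart-home log; seed %d", sim$spec$seed))
  jsonlite::write_json(list(habits = sim$truth$habits,
                            decoys = sim$truth$decoys,
                            labels = sim$truth$labels),
                       paste0(log_path, ".truth.json"), digits = NA,
                       auto_unbox = TRUE)
  yaml::write_yaml(unclass(sim$spec), paste0(log_path, ".spec.yaml"))
  invisible(log_path)
}
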