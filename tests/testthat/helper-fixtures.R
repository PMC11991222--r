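# Shared fixtures, all built in code.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Write a small CASAS log from plain lines and read it back
write_log_lines <- function(lines) {
  f <- tempfile(fileext = ".log")
  writeLines(lines, f)
  f
}

# A five-event toy stream: e2..e4 inside activity A
toy_events <- function() {
  read_events(write_log_lines(c(
    "2010-11-04 00:03:50.209589 M003 ON",
    "2010-11-04 00:03:55.000000 M003 OFF A begin",
    "2010-11-04 00:04:01.500000 M002 ON",
    "2010-11-04 00:04:05.000000 M002 OFF A end",
    "2010-11-04 00:04:10.000000 M001 ON")))
}

# Random well-formed event stream for round-trip property tests
random_events <- function(n, seed) {
  set.seed(seed)
  t0 <- as.numeric(ts_utc("2020-01-01 00:00:00"))
  tt <- sort(t0 + runif(n, 0, 86400 * 3))
  sid <- sample(c("M001", "M002", "D001", "T001"), n, replace = TRUE)
  val <- sample(c("ON", "OFF", "OPEN", "CLOSE", "21.5"), n, replace = TRUE)
  ev <- data.frame(timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
                   sensor_id = sid, value = val,
                   activity = NA_character_, boundary = NA_character_,
                   stringsAsFactors = FALSE)
  # wrap a random interior interval in begin/end
  if (n >= 4) {
    i <- sort(sample(2:(n - 1), 2))
    ev$activity[i] <- "Cooking"
    ev$boundary[i] <- c("begin", "end")
  }
  class(ev) <- c("casas_events", "data.frame")
  ev
}

# Random transaction database over <= n_items single-letter items
random_db <- function(n_items, n_tx, seed) {
  set.seed(seed)
  univ <- letters[seq_len(n_items)]
  lapply(seq_len(n_tx), function(i)
    sample(univ, sample.int(n_items, 1)))
}

# Tiny one-activity scenario: deterministic event count
tiny_spec <- function(n_days = 1, rate = 2, dur = 10, seed = 5L,
                      noise_rate = 0, adherence_slot = FALSE) {
  sensors <- data.frame(id = c("M001"), type = "motion",
                        stringsAsFactors = FALSE)
  acts <- list(Anything = list(sensors = "M001", rate = rate,
                               dur_mean_min = dur, dur_sdlog = 0.01))
  slots <- list(list(id = "s1", activity = "Anything", start = "09:00",
                     jitter_sd_min = 1))
  home_spec(sensors, acts, slots, noise_rate = noise_rate,
            ambient_per_day = 0, n_days = n_days, seed = seed)
}

# Two-activity scenario with one planted habit, for gap checks
habit_spec <- function(n_days = 30, adherence = 1, seed = 9L) {
  sensors <- data.frame(id = c("M001", "M002"), type = c("motion", "motion"),
                        stringsAsFactors = FALSE)
  acts <- list(
    A = list(sensors = "M001", rate = 2, dur_mean_min = 10, dur_sdlog = 0.01),
    B = list(sensors = "M002", rate = 2, dur_mean_min = 8, dur_sdlog = 0.01))
  slots <- list(
    list(id = "a", activity = "A", start = "08:00", jitter_sd_min = 2),
    list(id = "b", activity = "B", after = "a", gap_mean_min = 5,
         gap_sd_min = 1, adherence = adherence))
  home_spec(sensors, acts, slots, noise_rate = 0, ambient_per_day = 0,
            n_days = n_days, seed = seed)
}

# Tiny U-Net config for fast model tests
tiny_unet_cfg <- function(n_classes = 3)
  unet_config(embed_dim = 6, encoder_filters = c(4, 6, 8),
              decoder_filters = c(6, 4), n_classes = n_classes)

# Numerical gradient check helper: returns worst relative error over a
# sample of parameters (biases nudged off zero to avoid sitting exactly on
# the ReLU kink at all-zero padding inputs; the frozen embedding padding
# row is excluded)
grad_check <- function(model, idx, y, n_per_param = 4, eps = 1e-6, seed = 1) {
  set.seed(seed)
  flat <- habitminer:::.flat_params(model)
  for (nm in grep("\\.b$", names(flat), value = TRUE))
    flat[[nm]] <- rnorm(length(flat[[nm]]), sd = 0.05)
  model <- habitminer:::.unflat_params(model, flat)
  out <- habitminer:::model_forward(model, idx, y)
  fn <- function(f)
    habitminer:::model_forward(habitminer:::.unflat_params(model, f), idx, y)$loss
  worst <- 0
  for (nm in names(out$grads)) {
    n <- length(flat[[nm]])
    cand <- seq_len(n)
    if (nm == "emb") {
      nr <- nrow(flat[[nm]])
      cand <- cand[(cand - 1) %% nr != 0]   # skip frozen padding row
    }
    for (ix in sample(cand, min(n_per_param, length(cand)))) {
      f1 <- flat; f1[[nm]][ix] <- f1[[nm]][ix] + eps
      f2 <- flat; f2[[nm]][ix] <- f2[[nm]][ix] - eps
      ng <- (fn(f1) - fn(f2)) / (2 * eps)
      ag <- out$grads[[nm]][ix]
      if (abs(ng - ag) > 1e-8)
        worst <- max(worst, abs(ng - ag) / max(1e-6, abs(ng) + abs(ag)))
    }
  }
  worst
}
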