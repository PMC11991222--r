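# End-to-end orchestration: simulate -> preprocess -> train -> classify ->
# mine -> filter -> evaluate, with artifacts persisted per stage so any
# stage can be resumed from disk. A thin command-line front end lives in
# inst/cli/habitminer.

#' Pipeline configuration
#'
#' Defaults reproduce the default synthetic scenario end to end at desk
#' scale: SEW 25, depth-scaled U-Net with embedding, daily transactions
#' with 1-hour bins, support/confidence 0.8 and a 30-minute gap threshold.
#'
#' @param out_dir run directory (created if needed)
#' @param W sensor-event window size
#' @param step window stride
#' @param model \code{"unet"}, \code{"fcn"} or \code{"lstm"}
#' @param embedding learned embedding (TRUE) or one-hot input
#' @param depth_scale width multiplier for the network
#' @param epochs,patience,batch_size,lr training parameters
#' @param min_support,min_confidence mining thresholds (fractions)
#' @param max_gap_s temporal-filter threshold in seconds
#' @param min_run minimum windows per behavior run
#' @param bin_width_h hour-bin width for items
#' @param use_true_labels mine from ground-truth labels instead of
#'   classifier output (decouples the two halves)
#' @param include_other keep "Other"-labeled windows in training
#' @param scenario a \code{home_spec}; NULL with \code{log_path} set reads
#'   an existing CASAS log instead of simulating
#' @param log_path existing CASAS log (used when \code{scenario} is NULL)
#' @param seed master seed
#' @return a \code{pipeline_config}
#' @export
pipeline_config <- function(out_dir = tempfile("habitrun"), W = 25, step = 1,
                            model = "unet", embedding = TRUE,
                            depth_scale = 0.125, epochs = 8, patience = 3,
                            batch_size = 64, lr = 2e-3,
                            min_support = 0.8, min_confidence = 0.8,
                            max_gap_s = 1800, min_run = 3, bin_width_h = 1,
                            use_true_labels = FALSE, include_other = TRUE,
                            scenario = NULL, log_path = NULL, seed = 1L) {
  if (is.null(scenario) && is.null(log_path))
    scenario <- default_scenario(seed = seed)
  structure(list(out_dir = out_dir, W = W, step = step, model = model,
                 embedding = embedding, depth_scale = depth_scale,
                 epochs = epochs, patience = patience,
                 batch_size = batch_size, lr = lr,
                 min_support = min_support, min_confidence = min_confidence,
                 max_gap_s = max_gap_s, min_run = min_run,
                 bin_width_h = bin_width_h,
                 use_true_labels = use_true_labels,
                 include_other = include_other,
                 scenario = scenario, log_path = log_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Encode, window and split a labeled event stream
#'
#' Builds the vocabulary from the events covered by training windows only
#' (test-time unknowns map to UNK), encodes the full stream, segments it
#' into windows and returns the stratified split.
#'
#' @param events labeled \code{casas_events} (with a \code{label} column)
#' @param W,step windowing parameters
#' @param seed split seed
#' @param folds inner CV folds
#' @param numeric_bin_width temperature-token bin width
#' @return list(windows, vocab, split)
#' @export
prepare_dataset <- function(events, W, step = 1, seed = 1L, folds = 3,
                            numeric_bin_width = 5) {
  toks <- tokenize_event(events$sensor_id, events$value, numeric_bin_width)
  n <- length(toks)
  ends <- seq(min(step, n), n, by = step)
  if (ends[length(ends)] != n) ends <- c(ends, n)
  wlabels <- events$label[ends]
  split <- split_and_fold(wlabels, folds = folds, seed = seed)
  covered <- logical(n)
  for (e in ends[split$train_idx]) covered[max(1, e - W + 1):e] <- TRUE
  vocab <- build_vocabulary(toks[covered])
  idx <- encode_tokens(vocab, toks)
  windows <- segment_windows(idx, events$label, W, step,
                             timestamps = events$timestamp)
  list(windows = windows, vocab = vocab, split = split)
}

.stage_require <- function(stage, path, what) {
  if (!file.exists(path))
    stop(sprintf("stage '%s': required %s not found at %s", stage, what, path),
         call. = FALSE)
  path
}

#' Run the pipeline
#'
#' Stages run in order; each persists its artifacts under
#' \code{config$out_dir} and later stages reload them from disk when not
#' run in the same call, so any stage is resumable. Provenance (config +
#' seed + package version) is written alongside.
#'
#' @param config a \code{pipeline_config}
#' @param stages character vector out of simulate, preprocess, train,
#'   classify, mine, evaluate — or \code{"all"}
#' @param verbose print stage progress
#' @return list with the artifacts produced (invisibly also on disk):
#'   \code{eval_report}, \code{rules}, \code{habits}, \code{removed},
#'   \code{rule_eval_before}, \code{rule_eval_after}, \code{paths}
#' @export
run_pipeline <- function(config, stages = "all", verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "preprocess", "train", "classify", "mine",
                  "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list(paths = list())
  jsonlite::write_json(list(config = unclass(config)[setdiff(names(config), "scenario")],
                            package_version = as.character(utils::packageVersion("habitminer")),
                            r_version = R.version.string),
                       pth("provenance.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  events <- NULL; truth <- NULL
  if ("simulate" %in% stages) {
    say("stage simulate")
    if (is.null(config$scenario))
      stop("stage 'simulate': no scenario in config", call. = FALSE)
    sim <- generate_home(config$scenario)
    write_home(sim, pth("events.log"))
    events <- sim$events; truth <- sim$truth
  }
  load_events <- function(stage) {
    if (!is.null(events)) return(events)
    lp <- if (!is.null(config$log_path)) config$log_path else pth("events.log")
    .stage_require(stage, lp, "event log")
    ev <- read_events(lp)
    tj <- paste0(lp, ".truth.json")
    if (file.exists(tj)) {
      tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
      truth <<- tr
      if (!is.null(tr$labels)) ev$true_label <- tr$labels
    }
    events <<- ev
    ev
  }

  prep <- NULL
  if ("preprocess" %in% stages) {
    say("stage preprocess")
    ev <- load_events("preprocess")
    ev <- label_events(ev)
    prep <- prepare_dataset(ev, config$W, config$step, seed = config$seed)
    if (!config$include_other) {
      keep <- prep$windows$label != "Other"
      # split indices refer to window positions; recompute on the subset
      prep$windows <- prep$windows[keep]
      prep$split <- split_and_fold(prep$windows$label, seed = config$seed)
    }
    write_vocabulary(prep$vocab, pth("vocab.tsv"))
    utils::write.csv(cbind(as.data.frame(prep$windows$x),
                           label = prep$windows$label),
                     pth("windows.csv"), row.names = FALSE)
  }
  need_prep <- function(stage) {
    if (is.null(prep)) {
      ev <- load_events(stage)
      ev <- label_events(ev)
      prep <<- prepare_dataset(ev, config$W, config$step, seed = config$seed)
    }
    prep
  }

  model <- NULL
  if ("train" %in% stages) {
    say("stage train")
    p <- need_prep("train")
    classes <- sort(unique(p$windows$label))
    build_fn <- function(seed) switch(config$model,
      unet = build_unet(unet_config(n_classes = length(classes),
                                    depth_scale = config$depth_scale),
                        config$W, p$vocab$size, classes,
                        embedding = config$embedding, seed = seed),
      fcn = build_fcn(length(classes), p$vocab$size, classes,
                      embedding = config$embedding,
                      depth_scale = config$depth_scale, seed = seed),
      lstm = build_lstm(length(classes), p$vocab$size, classes,
                        embedding = config$embedding,
                        depth_scale = config$depth_scale, seed = seed),
      stop("unknown model: ", config$model))
    tr_idx <- p$split$train_idx
    val <- p$split$fold == 1
    m <- build_fn(config$seed)
    m <- train_with_early_stopping(m, p$windows[tr_idx[!val]],
                                   p$windows[tr_idx[val]],
                                   epochs = config$epochs,
                                   patience = config$patience,
                                   batch_size = config$batch_size,
                                   lr = config$lr, seed = config$seed,
                                   verbose = verbose)
    rep <- evaluate_model(m, p$windows[p$split$test_idx], seed = config$seed)
    write_eval_report(rep, pth("metrics.json"))
    save_checkpoint(m, pth("checkpoint.json"))
    res$eval_report <- rep
    model <- m
  }

  behaviors <- NULL
  if ("classify" %in% stages) {
    say("stage classify")
    p <- need_prep("classify")
    if (config$use_true_labels) {
      ev <- load_events("classify")
      behaviors <- behaviors_from_annotations(ev, config$bin_width_h)
    } else {
      if (is.null(model)) {
        .stage_require("classify", pth("checkpoint.json"), "model checkpoint")
        model <- load_checkpoint(pth("checkpoint.json"))
      }
      pred <- predict_windows(model, p$windows)
      behaviors <- windows_to_behaviors(pred$label, p$windows$end_timestamp,
                                        min_run = config$min_run,
                                        bin_width_h = config$bin_width_h)
    }
    bh <- behaviors
    bh$start_time <- format_casas_time(bh$start_time)
    bh$end_time <- format_casas_time(bh$end_time)
    utils::write.csv(bh, pth("behaviors.csv"), row.names = FALSE)
  }

  mined <- NULL; tx <- NULL
  if ("mine" %in% stages) {
    say("stage mine")
    if (is.null(behaviors)) {
      .stage_require("mine", pth("behaviors.csv"), "behaviors file")
      bh <- utils::read.csv(pth("behaviors.csv"), stringsAsFactors = FALSE)
      bh$start_time <- parse_casas_time(bh$start_time)
      bh$end_time <- parse_casas_time(bh$end_time)
      behaviors <- bh
    }
    tx <- build_transactions(behaviors)
    write_transactions(tx, pth("transactions.basket"))
    freq <- fp_growth(tx, config$min_support)
    rules <- generate_rules(freq, config$min_confidence)
    rules <- rule_gaps(rules, tx)
    flt <- temporal_filter(rules, tx, config$max_gap_s)
    write_habits(flt$habits, pth("habits.tsv"), removed = flt$removed)
    both <- rbind(flt$habits, flt$removed)
    jsonlite::write_json(
      data.frame(
        antecedent = vapply(both$antecedent, paste, "", collapse = ","),
        consequent = vapply(both$consequent, paste, "", collapse = ","),
        support = both$support, confidence = both$confidence,
        median_gap_s = both$median_gap_s, kept = both$kept),
      pth("habits.json"), digits = NA)
    res$rules <- rules
    res$habits <- flt$habits
    res$removed <- flt$removed
    mined <- list(rules = rules, flt = flt)
  }

  if ("evaluate" %in% stages) {
    say("stage evaluate")
    if (is.null(mined)) stop("stage 'evaluate': no mined rules in this run; ",
                             "run the 'mine' stage first", call. = FALSE)
    if (is.null(truth)) load_events("evaluate")
    if (!is.null(truth$habits) && nrow(truth$habits) > 0) {
      before <- evaluate_rules(mined$rules, truth$habits)
      after <- evaluate_rules(mined$flt$habits, truth$habits)
      res$rule_eval_before <- before
      res$rule_eval_after <- after
      jsonlite::write_json(
        list(before_filter = before[c("TP", "FP", "precision")],
             after_filter = after[c("TP", "FP", "precision")],
             habits_recovered = sum(after$matched),
             n_planted = nrow(truth$habits)),
        pth("rule_evaluation.json"), auto_unbox = TRUE, digits = NA)
    } else {
      message("no ground-truth habits available; rule evaluation skipped")
    }
  }
  res$paths <- as.list(list.files(config$out_dir, full.names = TRUE))
  invisible(res)
}

#' Support/confidence grid sweep
#'
#' Mines rules for every (min_support, min_confidence) combination,
#' applies the temporal filter, and reports rule counts and precision per
#' cell plus grid means — the shape of the published sensitivity analysis
#' (grids 0.75–0.85 with 20 values each).
#'
#' @param transactions a \code{habit_transactions}
#' @param ground_truth planted-habit table (or NULL: counts only)
#' @param supports,confidences threshold grids
#' @param max_gap_s temporal-filter threshold
#' @return list(grid = data.frame per cell, means = list of grid means)
#' @export
grid_mine <- function(transactions, ground_truth = NULL,
                      supports = seq(0.75, 0.85, length.out = 20),
                      confidences = seq(0.75, 0.85, length.out = 20),
                      max_gap_s = 1800) {
  rows <- list()
  for (s in supports) {
    freq <- fp_growth(transactions, s)
    for (cf in confidences) {
      rules <- generate_rules(freq, cf)
      rules <- rule_gaps(rules, transactions)
      flt <- temporal_filter(rules, transactions, max_gap_s)
      row <- data.frame(min_support = s, min_confidence = cf,
                        n_rules = nrow(rules), n_habits = nrow(flt$habits))
      if (!is.null(ground_truth)) {
        ev <- evaluate_rules(flt$habits, ground_truth)
        row$TP <- ev$TP; row$FP <- ev$FP; row$precision <- ev$precision
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  grid <- do.call(rbind, rows)
  means <- list(mean_rules = mean(grid$n_rules),
                mean_habits = mean(grid$n_habits))
  if (!is.null(ground_truth)) {
    means$mean_TP <- mean(grid$TP)
    means$mean_precision <- mean(grid$precision, na.rm = TRUE)
  }
  list(grid = grid, means = means)
}
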