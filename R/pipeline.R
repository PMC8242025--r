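# End-to-end orchestration.  Each stage reads its inputs from the artifact
# directory and writes its outputs there, so running the stages one by one
# is equivalent to run_pipeline(); every stage derives its own seed
# substream from the master seed.

stage_seed <- function(config, stage, k = 0L) derive_seed(config$seed, stage, k)

artifact <- function(dir, ...) file.path(dir, ...)

#' Preprocess and average one subject's EEG
#'
#' The full single-subject chain: synthesize the continuous recording,
#' re-reference to the mastoid mean, epoch, reject artifacts by
#' peak-to-peak threshold and baseline-correct.
#'
#' @param trials_s flagged trial table of one subject.
#' @param effects an [effect_params()].
#' @param config a [paradigm_config()].
#' @param preproc preprocessing parameter list (see [pipeline_config()]).
#' @param seed integer seed for the recording synthesis.
#' @return List with the cleaned `epochs` and the `rejection` report.
#' @export
preprocess_subject <- function(trials_s, effects, config,
                               preproc = pipeline_defaults()$preprocessing,
                               seed = 1L) {
  rec <- synthesize_recording(trials_s, effects, config, seed = seed)
  rec <- rereference(rec, weight = preproc$mastoid_weight,
                     mastoid_left = config$mastoid_channels[["left"]])
  ep <- extract_epochs(rec, trials_s, preproc$epoch_window_ms)
  rej <- reject_artifacts(ep, preproc$reject_threshold_uv,
                          exclude_channels = unname(config$mastoid_channels))
  ep <- baseline_correct(rej$epochs, preproc$baseline_ms)
  list(epochs = ep, rejection = rej$report)
}

# Pooled-channel conditional waveform for a set of trial uids; NULL when
# no epoch survives for the bin.
pooled_bin_waveform <- function(epochs, uids, channels, label) {
  sel <- which(epochs$trial_ids %in% uids)
  if (length(sel) == 0L) return(NULL)
  pool_channels(average_trials(epochs, uids, label), channels)
}

subject_waveform_rows <- function(trials_s, epochs, config, splits_cfg) {
  channels <- config$analysis_channels
  rows <- list()
  add <- function(set, task, type, tag, w) {
    if (is.null(w)) return()
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      subject = trials_s$subject[1], set = set, task = task,
      trial_type = type, tag = tag, n_trials = sum(w$n_trials),
      time_ms = w$time_ms, amp = w$data[1L, ])
  }
  eligible <- trials_s[trials_s$erp_eligible, , drop = FALSE]
  for (task in config$tasks) {
    for (type in c("PC", "DC", "nontarget")) {
      uids <- eligible$uid[eligible$task == task & eligible$trial_type == type]
      add("cell", task, type, "all",
          pooled_bin_waveform(epochs, uids, channels,
                              list(task = task, trial_type = type)))
    }
  }
  med <- median_rt_split(trials_s, tie = splits_cfg$median_tie)
  rep_split <- repetition_split(trials_s)
  quart <- quartile_rt_split(trials_s)
  bin_uids <- function(assign, tag, task, type) {
    tagged <- assign$uid[assign$tag == tag]
    eligible$uid[eligible$uid %in% tagged & eligible$task == task &
                   eligible$trial_type == type]
  }
  for (type in c("PC", "DC", "nontarget")) {
    for (tag in c("fast", "slow")) {
      add("median_rt", "color", type, tag,
          pooled_bin_waveform(epochs, bin_uids(med, tag, "color", type),
                              channels, list(task = "color", trial_type = type)))
    }
    for (tag in c("repeat", "switch")) {
      add("repetition", "color", type, tag,
          pooled_bin_waveform(epochs, bin_uids(rep_split, tag, "color", type),
                              channels, list(task = "color", trial_type = type)))
    }
  }
  for (type in c("DC", "nontarget")) {
    for (tag in paste0("Q", 1:4)) {
      add("quartile_rt", "color", type, tag,
          pooled_bin_waveform(epochs, bin_uids(quart, tag, "color", type),
                              channels, list(task = "color", trial_type = type)))
    }
  }
  data.table::rbindlist(rows)
}

#' Pipeline stage: simulate trials and behaviour
#'
#' Designs the trial tables for every subject, simulates reaction times and
#' accuracy, flags invalid trials, and writes `trials.tsv`,
#' `behavior.tsv` (the 2 x 3 task by trial-type summary) and
#' `behavior.json` (the behavioural repeated-measures ANOVAs).
#'
#' @param config a [pipeline_config()].
#' @param dir artifact directory.
#' @return List of the stage artifacts, invisibly.
#' @export
pipeline_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- simulate_dataset(config$paradigm, config$effects,
                             seed = stage_seed(config, 1L))
  trials <- filter_behavior(trials)
  write_trials(trials, artifact(dir, "trials.tsv"))
  summary <- summarize_behavior(trials)
  data.table::fwrite(summary, artifact(dir, "behavior.tsv"), sep = "\t")
  anovas <- behavior_anovas(trials)
  jsonlite::write_json(list(rt = as.data.frame(anovas$rt),
                            accuracy = as.data.frame(anovas$accuracy)),
                       artifact(dir, "behavior.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trials = trials, summary = summary, anovas = anovas))
}

# Subject x cell behavioural matrices and their 2 x 3 rANOVAs.
behavior_anovas <- function(trials) {
  dt <- data.table::as.data.table(trials)
  dt <- dt[trial_type %in% c("PC", "DC", "nontarget")]
  dt[, valid := !invalid_rt & !anticipatory & !delayed]
  agg <- dt[, list(rt = mean(rt_ms[valid & correct]),
                   acc = 100 * mean(correct[valid])),
            by = list(subject, task, trial_type)]
  agg <- as.data.frame(agg)
  tasks <- sort(unique(agg$task))
  types <- c("PC", "DC", "nontarget")
  subjects <- sort(unique(agg$subject))
  to_matrix <- function(col) {
    m <- matrix(NA_real_, length(subjects), 6L)
    k <- 0L
    for (tk in tasks) for (ty in types) {
      k <- k + 1L
      sel <- agg[agg$task == tk & agg$trial_type == ty, ]
      m[match(sel$subject, subjects), k] <- sel[[col]]
    }
    m
  }
  list(rt = rm_anova(to_matrix("rt"), 2L, 3L, c("TASK", "COLOR")),
       accuracy = rm_anova(to_matrix("acc"), 2L, 3L, c("TASK", "COLOR")))
}

#' Pipeline stage: EEG synthesis, preprocessing and condition averaging
#'
#' Runs the single-subject chain ([preprocess_subject()]) for every
#' subject, computes pooled-channel condition averages for the 2 x 3 cells
#' and for the RT-median, target-repetition and RT-quartile bins, and
#' writes `waveforms.tsv` (long format) and `rejections.tsv`.
#'
#' @inheritParams pipeline_simulate
#' @return Invisible list with the waveform table and rejection summary.
#' @export
pipeline_erp <- function(config, dir) {
  trials <- read_trials(artifact(dir, "trials.tsv"))
  subjects <- sort(unique(trials$subject))
  waves <- list()
  rej <- list()
  for (s in subjects) {
    trials_s <- trials[trials$subject == s, , drop = FALSE]
    res <- preprocess_subject(trials_s, config$effects, config$paradigm,
                              config$preprocessing,
                              seed = stage_seed(config, 2L, s))
    waves[[s]] <- subject_waveform_rows(trials_s, res$epochs,
                                        config$paradigm, config$splits)
    rej[[s]] <- data.table::data.table(subject = s,
                                       n_epochs = nrow(res$rejection$table),
                                       fraction = res$rejection$fraction)
  }
  waveforms <- data.table::rbindlist(waves)
  rejections <- data.table::rbindlist(rej)
  data.table::fwrite(waveforms, artifact(dir, "waveforms.tsv"), sep = "\t")
  data.table::fwrite(rejections, artifact(dir, "rejections.tsv"), sep = "\t")
  invisible(list(waveforms = waveforms, rejections = rejections))
}

# Rebuild the subjects x cells x samples array of one waveform set.
waveform_array <- function(waveforms, set_name, tags, tasks, types) {
  wf <- waveforms[waveforms$set == set_name, ]
  time_ms <- sort(unique(wf$time_ms))
  subjects <- sort(unique(wf$subject))
  combos <- expand.grid(type = types, tag = tags, task = tasks,
                        stringsAsFactors = FALSE)
  # order: task major, then tag, then type
  combos <- combos[order(match(combos$task, tasks), match(combos$tag, tags),
                         match(combos$type, types)), ]
  arr <- array(NA_real_, dim = c(length(subjects), nrow(combos),
                                 length(time_ms)))
  for (k in seq_len(nrow(combos))) {
    sel <- wf[wf$task == combos$task[k] & wf$tag == combos$tag[k] &
                wf$trial_type == combos$type[k], ]
    for (s in unique(sel$subject)) {
      rows <- sel[sel$subject == s, ]
      arr[match(s, subjects), k, ] <- rows$amp[order(rows$time_ms)]
    }
  }
  list(cells = arr, time_ms = time_ms, combos = combos, subjects = subjects)
}

#' Pipeline stage: sliding-window statistics
#'
#' Runs the sliding 2 x 3 repeated-measures ANOVA (factors TASK and COLOR)
#' over the per-subject cell waveforms and writes the per-sample p-value
#' series (`pvalues.tsv`) and the detected intervals (`stats.json`).
#'
#' @inheritParams pipeline_simulate
#' @return Invisible `sliding_result`.
#' @export
pipeline_stats <- function(config, dir) {
  waveforms <- as.data.frame(read_body(artifact(dir, "waveforms.tsv")))
  arr <- waveform_array(waveforms, "cell", tags = "all",
                        tasks = config$paradigm$tasks,
                        types = c("PC", "DC", "nontarget"))
  if (anyNA(arr$cells)) stop_config("incomplete cell waveforms; rerun the erp stage")
  st <- config$stats
  scan <- sliding_anova(arr$cells, arr$time_ms,
                        range_ms = st$range_ms,
                        window_samples = st$window_samples,
                        alpha0 = st$alpha0, fc = st$lowpass_fc,
                        use_gg = st$use_gg, min_run = st$min_run)
  pv <- data.table::data.table(time_ms = scan$anchor_ms)
  for (e in colnames(scan$p)) pv[[e]] <- scan$p[, e]
  data.table::fwrite(pv, artifact(dir, "pvalues.tsv"), sep = "\t")
  jsonlite::write_json(
    list(alpha = scan$alpha,
         window_ms = scan$window_samples * 1000 /
           (1000 / stats::median(diff(arr$time_ms))),
         window_samples = scan$window_samples,
         range_ms = scan$range_ms,
         intervals = lapply(scan$intervals, as.data.frame)),
    artifact(dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(scan)
}

#' Pipeline stage: RT-split and repetition analyses
#'
#' Derives, per subject, the early- and late-window mean amplitudes of the
#' DC minus nontarget difference wave for fast and slow median-split
#' responses and tests the EARLYLATE x FASTSLOW interaction; summarises the
#' per-quartile early amplitudes; and recovers the target-repetition RT
#' benefit with a paired t-test.  Writes `splits.tsv` (trial assignments),
#' `split_amplitudes.tsv` and `splits.json`.
#'
#' @inheritParams pipeline_simulate
#' @param early_window_ms,late_window_ms amplitude windows in ms (defaults:
#'   the canonical early/late GFBA ranges).
#' @return Invisible list of split results.
#' @export
pipeline_splits <- function(config, dir, early_window_ms = c(73, 96),
                            late_window_ms = c(167, 254)) {
  trials <- read_trials(artifact(dir, "trials.tsv"))
  waveforms <- as.data.frame(read_body(artifact(dir, "waveforms.tsv")))
  assignments <- rbind(median_rt_split(trials, tie = config$splits$median_tie),
                       quartile_rt_split(trials),
                       repetition_split(trials))
  write_split_assignment(assignments, artifact(dir, "splits.tsv"))

  diff_amp <- function(set, tag, window, s) {
    get_amp <- function(type) {
      sel <- waveforms[waveforms$set == set & waveforms$subject == s &
                         waveforms$tag == tag & waveforms$trial_type == type, ]
      if (nrow(sel) == 0L) return(NA_real_)
      idx <- time_window_idx(sel$time_ms[order(sel$time_ms)], window)
      mean(sel$amp[order(sel$time_ms)][idx])
    }
    get_amp("DC") - get_amp("nontarget")
  }
  subjects <- sort(unique(waveforms$subject))
  amp_tab <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject = s,
               early_fast = diff_amp("median_rt", "fast", early_window_ms, s),
               early_slow = diff_amp("median_rt", "slow", early_window_ms, s),
               late_fast = diff_amp("median_rt", "fast", late_window_ms, s),
               late_slow = diff_amp("median_rt", "slow", late_window_ms, s))
  }))
  data.table::fwrite(amp_tab, artifact(dir, "split_amplitudes.tsv"), sep = "\t")
  complete <- stats::complete.cases(amp_tab)
  interaction <- if (sum(complete) >= 2L) {
    split_interaction_anova(as.matrix(amp_tab[complete, -1]))
  } else {
    NULL
  }
  quart_amp <- sapply(paste0("Q", 1:4), function(q) {
    vals <- sapply(subjects, function(s) {
      diff_amp("quartile_rt", q, early_window_ms, s)
    })
    mean(vals, na.rm = TRUE)
  })
  # repetition benefit on behaviour: correct in-range trials only
  el <- trials[trials$erp_eligible & trials$repetition != "undefined", ]
  per_subj <- do.call(rbind, lapply(sort(unique(el$subject)), function(s) {
    es <- el[el$subject == s, ]
    data.frame(subject = s,
               rt_repeat = mean(es$rt_ms[es$repetition == "repeat"]),
               rt_switch = mean(es$rt_ms[es$repetition == "switch"]))
  }))
  rep_t <- if (nrow(per_subj) >= 2L) {
    paired_t(per_subj$rt_switch, per_subj$rt_repeat)
  } else {
    NULL
  }
  out <- list(median_interaction = if (!is.null(interaction)) as.data.frame(interaction),
              quartile_early_amp = as.list(quart_amp),
              repetition_benefit_ms = if (!is.null(rep_t)) rep_t$mean_diff,
              repetition_t = rep_t,
              early_window_ms = early_window_ms,
              late_window_ms = late_window_ms)
  jsonlite::write_json(out, artifact(dir, "splits.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(c(out, list(amplitudes = amp_tab, assignments = assignments)))
}

#' Pipeline stage: toy source localization
#'
#' Builds a toy leadfield, forward-projects the grand-average color-task DC
#' minus nontarget difference wave from a single source, recovers it with
#' the MNLS inverse, and reports the localization error (in source-index
#' steps), the ROI source waveform peak latency and the sensor-repositioning
#' residual.  Writes `source.json`.
#'
#' @inheritParams pipeline_simulate
#' @return Invisible list of source metrics.
#' @export
pipeline_source <- function(config, dir) {
  src <- config$source
  if (!isTRUE(src$enabled)) return(invisible(NULL))
  waveforms <- as.data.frame(read_body(artifact(dir, "waveforms.tsv")))
  wf <- waveforms[waveforms$set == "cell" & waveforms$task == "color", ]
  time_ms <- sort(unique(wf$time_ms))
  gmean <- function(type) {
    sel <- wf[wf$trial_type == type, ]
    agg <- tapply(sel$amp, sel$time_ms, mean)
    as.numeric(agg[as.character(time_ms)])
  }
  course <- gmean("DC") - gmean("nontarget")
  L <- make_toy_leadfield(src$n_sensors, src$n_sources, src$mode,
                          seed = stage_seed(config, 4L))
  lambda <- src$lambda %||% default_lambda(L)
  true_source <- min(max(1L, src$true_source), ncol(L$gain))
  x <- L$gain[, true_source, drop = FALSE] %*% matrix(course, 1L)
  W <- mnls_operator(L, lambda)
  est <- apply_inverse(W, x, time_ms = time_ms, lambda = lambda)
  strength <- rowMeans(abs(est$amplitudes))
  found <- which.max(strength)
  n_src <- ncol(L$gain)
  steps <- min(abs(found - true_source), n_src - abs(found - true_source))
  roi <- rois_from_maxima(est, 0.5)[[1]]
  roi_course <- roi_waveform(est, roi)
  # individual array: same ring, sensors rotated by half a sensor spacing
  L_ind <- make_toy_leadfield(src$n_sensors, src$n_sources, src$mode,
                              seed = stage_seed(config, 5L),
                              rotation = pi / src$n_sensors)
  x_ind <- L_ind$gain[, true_source, drop = FALSE] %*% matrix(course, 1L)
  x_canon <- reposition_sensors(x_ind, L_ind, L,
                                lambda = default_lambda(L_ind) * 1e-4)
  repos_err <- sqrt(sum((x_canon - x)^2) / sum(x^2))
  write_leadfield(L, artifact(dir, "leadfield"))
  out <- list(lambda = lambda, true_source = true_source,
              localized_source = unname(found),
              localization_error_steps = unname(steps),
              roi_label = roi$label,
              roi_peak_ms = time_ms[which.max(roi_course)],
              reposition_rel_error = repos_err)
  jsonlite::write_json(out, artifact(dir, "source.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Pipeline stage: collect the run report
#'
#' Gathers the per-stage artifacts into one machine-readable report
#' (`report.json`) with trial counts, rejection fractions, the behavioural
#' summary, detected significance intervals, split results, source metrics,
#' the package version and a configuration hash.
#'
#' @inheritParams pipeline_simulate
#' @param plot when `TRUE`, also writes `difference_waves.png`.
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(config, dir, plot = FALSE) {
  trials <- read_trials(artifact(dir, "trials.tsv"))
  behavior <- as.data.frame(read_body(artifact(dir, "behavior.tsv")))
  rejections <- as.data.frame(read_body(artifact(dir, "rejections.tsv")))
  stats_json <- jsonlite::read_json(artifact(dir, "stats.json"),
                                    simplifyVector = TRUE)
  splits_json <- jsonlite::read_json(artifact(dir, "splits.json"),
                                     simplifyVector = TRUE)
  source_path <- artifact(dir, "source.json")
  source_json <- if (file.exists(source_path)) {
    jsonlite::read_json(source_path, simplifyVector = TRUE)
  }
  cfg_file <- artifact(dir, "config.yaml")
  write_config(config, cfg_file)
  report <- list(
    package_version = as.character(utils::packageVersion("gfbascan")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    n_subjects = length(unique(trials$subject)),
    n_trials = nrow(trials),
    erp_eligible_fraction = mean(trials$erp_eligible),
    rejection_fraction_mean = mean(rejections$fraction),
    behavior = behavior,
    tested_windows_ms = list(early = splits_json$early_window_ms,
                             late = splits_json$late_window_ms),
    stats = stats_json,
    splits = splits_json,
    source = source_json)
  write_report(report, artifact(dir, "report.json"))
  if (plot) {
    plot_pipeline_waves(dir, artifact(dir, "difference_waves.png"))
  }
  invisible(report)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, erp, stats, splits, source and report in order,
#' sharing one artifact directory, and returns the report.  Rerunning with
#' the same configuration and seed reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @param dir artifact directory (a temporary directory by default).
#' @param plot write summary figures (default FALSE).
#' @return The run report list, invisibly.
#' @export
run_pipeline <- function(config, dir = tempfile("gfba-run-"), plot = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("'config' must be a pipeline_config")
  }
  pipeline_simulate(config, dir)
  pipeline_erp(config, dir)
  pipeline_stats(config, dir)
  pipeline_splits(config, dir)
  pipeline_source(config, dir)
  pipeline_report(config, dir, plot = plot)
}
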