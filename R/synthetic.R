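#' Design the trial sequence of the unattended probe experiment
#'
#' Builds the per-subject trial table: block order follows the
#' pseudorandomization constraint that the target-color pair is never
#' repeated on subsequent blocks and the task changes every second block,
#' with the four possible orders cycled across subjects.  Within a block the
#' target color is drawn uniformly from the block's pair, the probe color
#' uniformly from the five probe colors and the target orientation uniformly
#' from left/right, all independently.  Onset times accumulate the stimulus
#' duration plus a uniform inter-stimulus interval (blocks are separated by a
#' short pause).
#'
#' Trial types follow from the block's pair: `PC` if the probe matches the
#' present target color, `DC` if it matches the other (distracting
#' alternative) member of the pair, `magenta` for the never-target color and
#' `nontarget` otherwise.  The `repetition` tag is `repeat` when the target
#' color equals that of the previous trial in the same block, `switch`
#' otherwise, and `undefined` on each block's first trial.
#'
#' @param config a [paradigm_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return A `data.frame` with one row per trial: subject, task, block
#'   (session index), block_in_task, trial, uid (unique within subject),
#'   onset_s, color_pair, target_color, probe_color, target_orientation,
#'   trial_type, repetition; `rt_ms` and `correct` are unset (`NA`).
#' @export
design_trials <- function(config, seed = config$seed) {
  validate_paradigm(config)
  cols <- c("subject", "task", "block", "block_in_task", "trial", "uid",
            "onset_s", "color_pair", "target_color", "probe_color",
            "target_orientation", "trial_type", "repetition", "rt_ms", "correct")
  if (config$blocks_per_task == 0L || config$trials_per_block == 0L ||
      config$n_subjects == 0L) {
    empty <- stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    return(empty)
  }
  with_seed(seed, {
    out <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      out[[s]] <- design_subject(config, s)
    }
    do.call(rbind, out)
  })
}

design_subject <- function(config, subject) {
  n_blocks <- 2L * config$blocks_per_task
  ntb <- config$trials_per_block
  # four pseudorandomized orders cycled across subjects
  order_id <- (subject - 1L) %% 4L
  task_first <- config$tasks[order_id %% 2L + 1L]
  pair_first <- order_id %/% 2L + 1L
  task_other <- setdiff(config$tasks, task_first)
  task_seq <- rep(rep(c(task_first, task_other), each = 2L),
                  length.out = n_blocks)           # task changes every 2nd block
  pair_seq <- rep(c(pair_first, 3L - pair_first),
                  length.out = n_blocks)           # pair alternates every block
  extra <- extra_probe_color(config)
  block_gap_s <- 2                                  # pause between blocks
  t_now <- 2                                        # lead-in before first trial
  rows <- vector("list", n_blocks)
  block_in_task <- stats::setNames(c(0L, 0L), config$tasks)
  for (b in seq_len(n_blocks)) {
    task <- task_seq[b]
    block_in_task[task] <- block_in_task[task] + 1L
    pair <- config$target_color_pairs[[pair_seq[b]]]
    target <- sample(pair, ntb, replace = TRUE)
    probe <- sample(config$probe_colors, ntb, replace = TRUE)
    orient <- sample(c("left", "right"), ntb, replace = TRUE)
    isi_s <- stats::runif(ntb, config$isi_range_ms[1], config$isi_range_ms[2]) / 1000
    onset <- t_now + cumsum(c(0, (config$stimulus_duration_ms / 1000 + isi_s)[-ntb]))
    t_now <- onset[ntb] + config$stimulus_duration_ms / 1000 + isi_s[ntb] + block_gap_s
    other <- ifelse(target == pair[1], pair[2], pair[1])
    type <- ifelse(probe == target, "PC",
                   ifelse(probe == other, "DC",
                          ifelse(probe == extra, "magenta", "nontarget")))
    repetition <- c("undefined",
                    ifelse(target[-1] == target[-ntb], "repeat", "switch"))
    rows[[b]] <- data.frame(subject = subject, task = task, block = b,
                            block_in_task = unname(block_in_task[task]),
                            trial = seq_len(ntb), uid = 0L, onset_s = onset,
                            color_pair = paste(pair, collapse = "-"),
                            target_color = target, probe_color = probe,
                            target_orientation = orient, trial_type = type,
                            repetition = repetition, rt_ms = NA_real_,
                            correct = NA, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$uid <- seq_len(nrow(res))
  res
}

#' Simulate behavioral outcomes (reaction times and accuracy)
#'
#' Reaction times follow
#' `rt = rt_base_mean + dc_rt_cost * I(DC trial in color task)
#'  - repetition_benefit * I(target repeat)
#'  + early_amp_rt_coupling * eta + Gaussian noise`,
#' truncated at 50 ms, where `eta` is the per-trial deviate of the early DC
#' amplitude.  The same `eta` is consumed by [synthesize_recording()] /
#' [synthesize_epochs()], which is what couples a larger-magnitude (more
#' negative) early deflection to a faster response.  Correctness is Bernoulli
#' with the configured accuracy.
#'
#' @param trials a designed trial table (see [design_trials()]).
#' @param effects an [effect_params()].
#' @param seed integer seed.
#' @return `trials` with `rt_ms`, `correct` and the coupling deviate
#'   `early_amp_dev` (nonzero only where the early DC component exists,
#'   i.e. on color-task DC trials) filled in.
#' @export
simulate_behavior <- function(trials, effects, seed = 1L) {
  validate_effects(effects)
  n <- nrow(trials)
  if (n == 0L) {
    trials$early_amp_dev <- numeric(0)
    return(trials)
  }
  with_seed(seed, {
    has_early <- trials$trial_type == "DC" & trials$task == "color"
    eta <- stats::rnorm(n, 0, effects$early_amp_jitter_sd) * as.numeric(has_early)
    rt <- effects$rt_base_mean +
      effects$dc_rt_cost * as.numeric(has_early) -
      effects$repetition_benefit * as.numeric(trials$repetition == "repeat") +
      effects$early_amp_rt_coupling * eta +
      stats::rnorm(n, 0, effects$rt_base_sd)
    trials$rt_ms <- pmax(rt, 50)
    trials$correct <- stats::runif(n) < effects$accuracy_rate
    trials$early_amp_dev <- eta
    trials
  })
}

# Fixed probe-evoked template evaluated at epoch-relative times (ms).
erp_template <- function(t_ms, tpl) {
  tpl$p1_amp * exp(-(t_ms - tpl$p1_lat)^2 / (2 * tpl$p1_sd^2)) +
    tpl$n1_amp * exp(-(t_ms - tpl$n1_lat)^2 / (2 * tpl$n1_sd^2))
}

# Per-trial condition-delta amplitudes; returns list(early, late) vectors.
condition_amplitudes <- function(trials, effects) {
  is_color <- trials$task == "color"
  is_dc_color <- is_color & trials$trial_type == "DC"
  eta <- trials$early_amp_dev %||% rep(0, nrow(trials))
  early <- (effects$early_dc_amp + eta) * as.numeric(is_dc_color)
  late <- ifelse(trials$trial_type == "PC",
                 effects$late_pc_amp *
                   ifelse(is_color, 1, effects$orientation_task_pc_scale),
                 ifelse(is_dc_color, effects$late_dc_amp, 0))
  list(early = early, late = late)
}

check_effect_windows <- function(effects, time_ms) {
  for (w in list(effects$early_dc_window, effects$late_pc_window)) {
    if (length(time_window_idx(time_ms, w)) == 0L) {
      stop_config("effect window [", w[1], ", ", w[2],
                  ") ms lies outside the epoch support")
    }
  }
}

#' Synthesize a continuous multichannel EEG recording for one subject
#'
#' Produces a continuous recording (channels x samples, microvolts) with
#' white + 1/f noise on every channel, the fixed probe-evoked template plus
#' condition deltas added at the analysis channels around each stimulus
#' onset, blink transients on all non-mastoid channels at randomly chosen
#' (or caller-specified) trials, and noise only at the mastoids.  The
#' condition deltas are boxcar offsets over the configured effect windows;
#' the early DC amplitude of each trial is `early_dc_amp + early_amp_dev`,
#' reusing the deviate drawn by [simulate_behavior()] so that EEG amplitude
#' and reaction time stay coupled.
#'
#' @param trials trial table of a single subject carrying `rt_ms` (i.e.
#'   after [simulate_behavior()]).
#' @param effects an [effect_params()].
#' @param config a [paradigm_config()].
#' @param seed integer seed.
#' @param blink_trials optional integer uids of trials that receive a blink
#'   transient; by default trials are drawn with probability `blink_rate`.
#' @return A list of class `continuous_recording` with elements `data`
#'   (channels x samples matrix, microvolts), `channels`, `sampling_rate`,
#'   and `events` (`data.frame` with 0-based `sample` and trial `uid`).
#' @export
synthesize_recording <- function(trials, effects, config, seed = 1L,
                                 blink_trials = NULL) {
  validate_effects(effects)
  validate_paradigm(config)
  if (length(unique(trials$subject)) > 1L) {
    stop_config("synthesize_recording expects trials of a single subject")
  }
  if (nrow(trials) && anyNA(trials$rt_ms)) {
    stop_config("trials must carry reaction times; run simulate_behavior() first")
  }
  fs <- config$sampling_rate
  n_ch <- length(config$recording_channels)
  n_samples <- as.integer(ceiling((max(trials$onset_s, 0) + 1.5) * fs))
  post <- seq.int(0L, max(epoch_sample_offsets(c(-200, 700), fs)))
  t_post <- post * 1000 / fs
  check_effect_windows(effects, t_post)
  with_seed(seed, {
    noise <- t(white_noise(n_samples, n_ch, effects$noise_white_sd) +
                 colored_noise(n_samples, n_ch, effects$noise_pink_sd,
                               effects$noise_pink_exponent))
    rownames(noise) <- config$recording_channels
    data <- noise
    k0 <- onset_sample(trials$onset_s, fs)
    amps <- condition_amplitudes(trials, effects)
    base <- erp_template(t_post, effects$template)
    early_box <- as.numeric(t_post >= effects$early_dc_window[1] - 1e-9 &
                              t_post < effects$early_dc_window[2] - 1e-9)
    late_box <- as.numeric(t_post >= effects$late_pc_window[1] - 1e-9 &
                             t_post < effects$late_pc_window[2] - 1e-9)
    ch_sig <- match(config$analysis_channels, config$recording_channels)
    for (i in seq_len(nrow(trials))) {
      idx <- k0[i] + post + 1L
      keep <- idx >= 1L & idx <= n_samples
      wave <- base + amps$early[i] * early_box + amps$late[i] * late_box
      for (ch in ch_sig) {
        data[ch, idx[keep]] <- data[ch, idx[keep]] + wave[keep]
      }
    }
    # blink transients: smooth high-amplitude bumps on all non-mastoid channels
    if (is.null(blink_trials)) {
      blink_trials <- trials$uid[stats::runif(nrow(trials)) < effects$blink_rate]
    }
    if (length(blink_trials)) {
      scalp <- setdiff(seq_len(n_ch),
                       match(config$mastoid_channels, config$recording_channels))
      bump <- effects$blink_amp * exp(-(t_post - 250)^2 / (2 * 50^2))
      for (uid in blink_trials) {
        i <- match(uid, trials$uid)
        if (is.na(i)) next
        idx <- k0[i] + post + 1L
        keep <- idx >= 1L & idx <= n_samples
        data[scalp, idx[keep]] <- sweep(data[scalp, idx[keep], drop = FALSE],
                                        2L, bump[keep], "+")
      }
    }
    structure(list(data = data,
                   channels = config$recording_channels,
                   sampling_rate = fs,
                   events = data.frame(sample = k0, uid = trials$uid)),
              class = "continuous_recording")
  })
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording> ", length(x$channels), " channels x ",
      ncol(x$data), " samples @ ", x$sampling_rate, " Hz, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Synthesize stimulus-locked epochs directly (one subject)
#'
#' Epoch-level variant of [synthesize_recording()]: the same probe-evoked
#' template, condition deltas, blink transients, and white + 1/f noise, but
#' generated per epoch on the standard epoch grid instead of cutting a
#' continuous recording.  Epoch noise is independent across trials (no
#' cross-epoch continuity).  Useful when the continuous-recording plumbing
#' itself is not under study.
#'
#' @inheritParams synthesize_recording
#' @param channels channels to synthesize (default: analysis channels).
#' @param window_ms epoch window in ms, left-closed right-open.
#' @return An `epoch_set` (see [extract_epochs()]); baseline not applied.
#' @export
synthesize_epochs <- function(trials, effects, config, seed = 1L,
                              channels = config$analysis_channels,
                              window_ms = c(-200, 700),
                              blink_trials = NULL) {
  validate_effects(effects)
  if (length(unique(trials$subject)) > 1L) {
    stop_config("synthesize_epochs expects trials of a single subject")
  }
  fs <- config$sampling_rate
  offs <- epoch_sample_offsets(window_ms, fs)
  time_ms <- offs * 1000 / fs
  check_effect_windows(effects, time_ms)
  ntr <- nrow(trials)
  ns <- length(offs)
  nch <- length(channels)
  with_seed(seed, {
    amps <- condition_amplitudes(trials, effects)
    base <- erp_template(time_ms, effects$template)
    early_box <- as.numeric(time_ms >= effects$early_dc_window[1] - 1e-9 &
                              time_ms < effects$early_dc_window[2] - 1e-9)
    late_box <- as.numeric(time_ms >= effects$late_pc_window[1] - 1e-9 &
                             time_ms < effects$late_pc_window[2] - 1e-9)
    # per-trial signal (ns x ntr); evoked activity starts at stimulus onset
    sig <- matrix(base, ns, ntr) +
      outer(early_box, amps$early) + outer(late_box, amps$late)
    if (is.null(blink_trials)) {
      blink_trials <- trials$uid[stats::runif(ntr) < effects$blink_rate]
    }
    bi <- match(blink_trials, trials$uid)
    bi <- bi[!is.na(bi)]
    if (length(bi)) {
      bump <- effects$blink_amp * exp(-(time_ms - 250)^2 / (2 * 50^2))
      sig[, bi] <- sig[, bi] + bump
    }
    sig[time_ms < 0, ] <- 0
    data <- array(0, dim = c(ntr, nch, ns))
    carries_signal <- channels %in% config$analysis_channels
    for (c_i in seq_len(nch)) {
      noise <- white_noise(ns, ntr, effects$noise_white_sd) +
        colored_noise(ns, ntr, effects$noise_pink_sd, effects$noise_pink_exponent)
      layer <- if (carries_signal[c_i]) noise + sig else noise
      data[, c_i, ] <- t(layer)
    }
    new_epoch_set(data, time_ms, channels, fs, trial_ids = trials$uid)
  })
}

#' Simulate trials and behaviour for a whole dataset
#'
#' Convenience wrapper: [design_trials()] followed by [simulate_behavior()],
#' with per-stage seeds derived from one master seed.
#'
#' @inheritParams design_trials
#' @param effects an [effect_params()].
#' @return The trial table with behaviour filled in.
#' @export
simulate_dataset <- function(config, effects, seed = config$seed) {
  trials <- design_trials(config, seed = derive_seed(seed, 1))
  simulate_behavior(trials, effects, seed = derive_seed(seed, 2))
}

#' Simulate per-subject condition-average waveforms directly
#'
#' Generates the pooled-channel (mean across analysis channels),
#' baseline-corrected condition averages that the sliding-window statistics
#' consume, without materialising single trials.  For Gaussian white + 1/f
#' noise the average of `n` independent noise epochs is distributed exactly
#' as one noise epoch scaled by `1/sqrt(n)`, so sampling the average
#' directly is a distributional identity, not an approximation.  The
#' per-condition trial counts are the expected counts after behavioural
#' filtering and blink rejection under the configured rates.
#'
#' @inheritParams simulate_dataset
#' @param n_subjects number of subjects (default from `config`).
#' @param baseline_ms baseline window subtracted per waveform.
#' @return A list with `cells` (array subjects x 6 cells x samples; cells
#'   ordered task-major: color PC/DC/nontarget then orientation
#'   PC/DC/nontarget), `time_ms`, `cell_labels` and `n_trials`.
#' @export
simulate_condition_averages <- function(config, effects, seed = config$seed,
                                        n_subjects = config$n_subjects,
                                        baseline_ms = c(-150, 0)) {
  validate_paradigm(config)
  validate_effects(effects)
  fs <- config$sampling_rate
  offs <- epoch_sample_offsets(c(-200, 700), fs)
  time_ms <- offs * 1000 / fs
  check_effect_windows(effects, time_ms)
  ns <- length(offs)
  n_per_task <- config$blocks_per_task * config$trials_per_block
  # expected usable trials: uniform probe (PC 1/5, DC 1/5, nontarget 2/5),
  # thinned by accuracy and blink rejection
  keep <- effects$accuracy_rate * (1 - effects$blink_rate)
  n_cell <- round(n_per_task / 5 * c(1, 1, 2) * keep)
  cell_labels <- data.frame(
    task = rep(config$tasks, each = 3L),
    trial_type = rep(c("PC", "DC", "nontarget"), 2L))
  base <- erp_template(time_ms, effects$template)
  early_box <- as.numeric(time_ms >= effects$early_dc_window[1] - 1e-9 &
                            time_ms < effects$early_dc_window[2] - 1e-9)
  late_box <- as.numeric(time_ms >= effects$late_pc_window[1] - 1e-9 &
                           time_ms < effects$late_pc_window[2] - 1e-9)
  mean_wave <- function(task, type) {
    early <- if (task == "color" && type == "DC") effects$early_dc_amp else 0
    late <- if (type == "PC") {
      effects$late_pc_amp * if (task == "color") 1 else effects$orientation_task_pc_scale
    } else if (task == "color" && type == "DC") effects$late_dc_amp else 0
    base + early * early_box + late * late_box
  }
  n_pool <- length(config$analysis_channels)
  with_seed(seed, {
    cells <- array(0, dim = c(n_subjects, 6L, ns))
    for (s in seq_len(n_subjects)) {
      for (cell in seq_len(6L)) {
        task <- cell_labels$task[cell]
        type <- cell_labels$trial_type[cell]
        n_tr <- n_cell[match(type, c("PC", "DC", "nontarget"))]
        shrink <- sqrt(n_tr * n_pool)
        wave <- mean_wave(task, type) +
          as.vector(white_noise(ns, 1L, effects$noise_white_sd / shrink)) +
          as.vector(colored_noise(ns, 1L, effects$noise_pink_sd / shrink,
                                  effects$noise_pink_exponent))
        if (task == "color" && type == "DC" && effects$early_amp_jitter_sd > 0) {
          wave <- wave + early_box *
            stats::rnorm(1L, 0, effects$early_amp_jitter_sd / sqrt(n_tr))
        }
        bl <- time_window_idx(time_ms, baseline_ms)
        cells[s, cell, ] <- wave - mean(wave[bl])
      }
    }
    list(cells = cells, time_ms = time_ms, cell_labels = cell_labels,
         n_trials = n_cell)
  })
}
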