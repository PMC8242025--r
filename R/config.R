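#' Paradigm configuration for the unattended probe experiment
#'
#' Describes the trial and block structure of the two-task unattended probe
#' paradigm: two tasks (color / orientation discrimination of the target),
#' two blockwise target-color pairs, and a task-irrelevant probe drawn from
#' five colors (the four target colors plus one color that is never a
#' target).  Defaults reproduce the canonical design: 6 blocks of 180 trials
#' per task, 300 ms stimuli, 1000--1200 ms uniform inter-stimulus intervals,
#' EEG digitized at 254.31 Hz, analysis channels PO3/PO7.
#'
#' @param n_subjects number of participants to simulate.
#' @param blocks_per_task experimental blocks per task.
#' @param trials_per_block trials within each block.
#' @param tasks character vector of the two task names.
#' @param target_color_pairs list of two character vectors, each one
#'   unordered pair of target colors assigned blockwise.
#' @param probe_colors the five probe colors; must contain all target colors
#'   plus exactly one extra (never-target) color.
#' @param sampling_rate EEG sampling frequency in Hz.
#' @param stimulus_duration_ms stimulus duration in ms.
#' @param isi_range_ms inter-stimulus interval range in ms (uniform draw).
#' @param analysis_channels channels pooled for the ERP analyses.
#' @param recording_channels all channels of the simulated montage; must
#'   include the analysis channels and both mastoids.
#' @param mastoid_channels named character vector with entries `left` and
#'   `right` giving the mastoid channel names.
#' @param seed default seed used when none is passed to the generators.
#' @return A validated list of class `paradigm_config`.
#' @export
paradigm_config <- function(n_subjects = 22L,
                            blocks_per_task = 6L,
                            trials_per_block = 180L,
                            tasks = c("color", "orientation"),
                            target_color_pairs = list(c("red", "green"),
                                                      c("blue", "yellow")),
                            probe_colors = c("red", "green", "blue",
                                             "yellow", "magenta"),
                            sampling_rate = 254.31,
                            stimulus_duration_ms = 300,
                            isi_range_ms = c(1000, 1200),
                            analysis_channels = c("PO3", "PO7"),
                            recording_channels = c("PO3", "PO7", "PO4", "PO8",
                                                   "Oz", "M1", "M2"),
                            mastoid_channels = c(left = "M1", right = "M2"),
                            seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              blocks_per_task = as.integer(blocks_per_task),
              trials_per_block = as.integer(trials_per_block),
              tasks = tasks,
              target_color_pairs = target_color_pairs,
              probe_colors = probe_colors,
              sampling_rate = sampling_rate,
              stimulus_duration_ms = stimulus_duration_ms,
              isi_range_ms = isi_range_ms,
              analysis_channels = analysis_channels,
              recording_channels = recording_channels,
              mastoid_channels = mastoid_channels,
              seed = as.integer(seed))
  class(cfg) <- "paradigm_config"
  validate_paradigm(cfg)
  cfg
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("<paradigm_config> ", x$n_subjects, " subjects, ",
      x$blocks_per_task, " x ", x$trials_per_block,
      " trials/task, fs = ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

validate_paradigm <- function(cfg) {
  check_number(cfg$n_subjects, "n_subjects", lower = 0)
  check_number(cfg$blocks_per_task, "blocks_per_task", lower = 0)
  check_number(cfg$trials_per_block, "trials_per_block", lower = 0)
  if (length(cfg$tasks) != 2L || anyDuplicated(cfg$tasks)) {
    stop_config("'tasks' must be two distinct task names")
  }
  if (!is.list(cfg$target_color_pairs) || length(cfg$target_color_pairs) != 2L ||
      any(lengths(cfg$target_color_pairs) != 2L)) {
    stop_config("'target_color_pairs' must be a list of two color pairs")
  }
  targets <- unlist(cfg$target_color_pairs)
  if (anyDuplicated(targets)) {
    stop_config("target colors must be distinct across the two pairs")
  }
  if (length(cfg$probe_colors) != 5L || anyDuplicated(cfg$probe_colors)) {
    stop_config("'probe_colors' must be five distinct colors")
  }
  if (!all(targets %in% cfg$probe_colors)) {
    stop_config("'probe_colors' must contain all four target colors")
  }
  if (length(setdiff(cfg$probe_colors, targets)) != 1L) {
    stop_config("'probe_colors' must add exactly one never-target color")
  }
  check_number(cfg$sampling_rate, "sampling_rate", lower = 1e-6)
  check_number(cfg$stimulus_duration_ms, "stimulus_duration_ms", lower = 0)
  check_interval(cfg$isi_range_ms, "isi_range_ms", lower = 0)
  if (!all(cfg$analysis_channels %in% cfg$recording_channels)) {
    stop_config("analysis channels must be part of the recording montage")
  }
  if (!all(c("left", "right") %in% names(cfg$mastoid_channels)) ||
      !all(cfg$mastoid_channels %in% cfg$recording_channels)) {
    stop_config("mastoid channels (left/right) must be named and present ",
                "in the recording montage")
  }
  if (anyDuplicated(cfg$recording_channels)) {
    stop_config("recording channel names must be unique")
  }
  invisible(cfg)
}

# The never-target probe color (magenta in the default palette).
extra_probe_color <- function(cfg) {
  setdiff(cfg$probe_colors, unlist(cfg$target_color_pairs))
}

#' Effect parameters of the synthetic ERP generator
#'
#' Amplitudes, latencies and noise levels of the simulated probe-evoked
#' response and of the injected attention effects.  The condition deltas are
#' flat (boxcar) offsets over their windows so that downstream averaging
#' recovers them exactly: an early negativity for distractor-color (DC)
#' probes in the color task only, and late negativities for present-target
#' color (PC) probes (both tasks; scaled down during the orientation task)
#' and color-task DC probes.  Reaction times carry a DC cost, a target
#' repetition benefit, and a per-trial coupling with the early DC amplitude
#' (larger-magnitude early negativity leading to faster responses).
#'
#' @param early_dc_window,late_pc_window ms windows of the early DC and late
#'   effects, within the epoch support.
#' @param early_dc_amp,late_pc_amp,late_dc_amp injected amplitudes in
#'   microvolts (negative).
#' @param orientation_task_pc_scale scaling in \[0, 1\] of the late PC effect
#'   during the orientation task.
#' @param early_amp_jitter_sd per-trial standard deviation (microvolts) of
#'   the early DC amplitude; the same deviate feeds the RT coupling.
#' @param rt_base_mean,rt_base_sd base reaction-time mean and noise sd (ms).
#' @param dc_rt_cost extra ms on color-task DC trials.
#' @param repetition_benefit ms saved when the target color repeats.
#' @param early_amp_rt_coupling ms per microvolt; positive values make a
#'   larger-magnitude (more negative) early deflection speed up the response.
#' @param accuracy_rate probability of a correct response.
#' @param noise_white_sd,noise_pink_sd,noise_pink_exponent single-trial noise
#'   model: white Gaussian sd, 1/f amplitude sd (both microvolts) and the 1/f
#'   spectral exponent.
#' @param blink_rate,blink_amp per-trial blink probability and blink
#'   amplitude in microvolts.
#' @param template list describing the fixed probe-evoked waveform (Gaussian
#'   P1/N1 deflections: amplitude in microvolts, latency and width in ms).
#' @return A validated list of class `effect_params`.
#' @export
effect_params <- function(early_dc_window = c(73, 96),
                          early_dc_amp = -0.8,
                          late_pc_window = c(167, 254),
                          late_pc_amp = -1.2,
                          late_dc_amp = -0.5,
                          orientation_task_pc_scale = 0.5,
                          early_amp_jitter_sd = 1.0,
                          rt_base_mean = 400,
                          rt_base_sd = 60,
                          dc_rt_cost = 25,
                          repetition_benefit = 40,
                          early_amp_rt_coupling = 20,
                          accuracy_rate = 0.95,
                          noise_white_sd = 8,
                          noise_pink_sd = 4,
                          noise_pink_exponent = 1,
                          blink_rate = 0.02,
                          blink_amp = 150,
                          template = list(p1_amp = 3, p1_lat = 100, p1_sd = 20,
                                          n1_amp = -4, n1_lat = 170, n1_sd = 30)) {
  eff <- list(early_dc_window = early_dc_window,
              early_dc_amp = early_dc_amp,
              late_pc_window = late_pc_window,
              late_pc_amp = late_pc_amp,
              late_dc_amp = late_dc_amp,
              orientation_task_pc_scale = orientation_task_pc_scale,
              early_amp_jitter_sd = early_amp_jitter_sd,
              rt_base_mean = rt_base_mean,
              rt_base_sd = rt_base_sd,
              dc_rt_cost = dc_rt_cost,
              repetition_benefit = repetition_benefit,
              early_amp_rt_coupling = early_amp_rt_coupling,
              accuracy_rate = accuracy_rate,
              noise_white_sd = noise_white_sd,
              noise_pink_sd = noise_pink_sd,
              noise_pink_exponent = noise_pink_exponent,
              blink_rate = blink_rate,
              blink_amp = blink_amp,
              template = template)
  class(eff) <- "effect_params"
  validate_effects(eff)
  eff
}

validate_effects <- function(eff) {
  check_interval(eff$early_dc_window, "early_dc_window", lower = -200, upper = 700)
  check_interval(eff$late_pc_window, "late_pc_window", lower = -200, upper = 700)
  check_number(eff$orientation_task_pc_scale, "orientation_task_pc_scale", 0, 1)
  check_number(eff$early_amp_jitter_sd, "early_amp_jitter_sd", lower = 0)
  check_number(eff$rt_base_sd, "rt_base_sd", lower = 0)
  check_number(eff$accuracy_rate, "accuracy_rate", 0, 1)
  check_number(eff$noise_white_sd, "noise_white_sd", lower = 0)
  check_number(eff$noise_pink_sd, "noise_pink_sd", lower = 0)
  check_number(eff$blink_rate, "blink_rate", 0, 1)
  for (f in c("early_dc_amp", "late_pc_amp", "late_dc_amp", "rt_base_mean",
              "dc_rt_cost", "repetition_benefit", "early_amp_rt_coupling",
              "noise_pink_exponent", "blink_amp")) {
    check_number(eff[[f]], f)
  }
  tpl <- eff$template
  need <- c("p1_amp", "p1_lat", "p1_sd", "n1_amp", "n1_lat", "n1_sd")
  if (!is.list(tpl) || !all(need %in% names(tpl))) {
    stop_config("'template' must list ", paste(need, collapse = ", "))
  }
  invisible(eff)
}

#' @export
print.effect_params <- function(x, ...) {
  cat("<effect_params> early DC ", x$early_dc_amp, " uV @ [",
      x$early_dc_window[1], ", ", x$early_dc_window[2], ") ms; late PC ",
      x$late_pc_amp, " / DC ", x$late_dc_amp, " uV @ [",
      x$late_pc_window[1], ", ", x$late_pc_window[2], ") ms\n", sep = "")
  invisible(x)
}

pipeline_defaults <- function() {
  list(preprocessing = list(epoch_window_ms = c(-200, 700),
                            baseline_ms = c(-150, 0),
                            reject_threshold_uv = 100,
                            mastoid_weight = 0.5),
       stats = list(alpha0 = 0.05,
                    lowpass_fc = 50,
                    range_ms = c(0, 300),
                    window_samples = 3L,
                    min_run = 5L,
                    use_gg = TRUE),
       splits = list(median_tie = "exclude"),
       source = list(enabled = TRUE,
                     n_sensors = 16L,
                     n_sources = 24L,
                     mode = "ring_geometry",
                     true_source = 6L,
                     lambda = NULL))
}

#' Full pipeline configuration
#'
#' Bundles the paradigm, the generator effect parameters and the analysis
#' parameters of every pipeline stage.  Unknown keys in any block are
#' rejected so that configuration typos cannot silently change an analysis.
#'
#' @param paradigm a [paradigm_config()].
#' @param effects an [effect_params()].
#' @param preprocessing,stats,splits,source named lists overriding individual
#'   stage defaults (see Details in the package vignette).
#' @param seed master seed; every stage derives its own substream from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paradigm = paradigm_config(),
                            effects = effect_params(),
                            preprocessing = list(),
                            stats = list(),
                            splits = list(),
                            source = list(),
                            seed = 1L) {
  defaults <- pipeline_defaults()
  merge_block <- function(block, user, name) {
    extra <- setdiff(names(user), names(block))
    if (length(extra)) {
      stop_config("unknown ", name, " option(s): ", paste(extra, collapse = ", "))
    }
    utils::modifyList(block, user)
  }
  if (!inherits(paradigm, "paradigm_config")) stop_config("'paradigm' must be a paradigm_config")
  if (!inherits(effects, "effect_params")) stop_config("'effects' must be an effect_params")
  validate_paradigm(paradigm)
  validate_effects(effects)
  cfg <- list(schema_version = SCHEMA_VERSION,
              paradigm = paradigm,
              effects = effects,
              preprocessing = merge_block(defaults$preprocessing, preprocessing, "preprocessing"),
              stats = merge_block(defaults$stats, stats, "stats"),
              splits = merge_block(defaults$splits, splits, "splits"),
              source = merge_block(defaults$source, source, "source"),
              seed = as.integer(seed))
  check_interval(cfg$preprocessing$epoch_window_ms, "epoch_window_ms")
  check_interval(cfg$preprocessing$baseline_ms, "baseline_ms")
  check_number(cfg$preprocessing$reject_threshold_uv, "reject_threshold_uv", lower = 1e-9)
  check_number(cfg$stats$alpha0, "alpha0", 1e-12, 1 - 1e-12)
  check_number(cfg$stats$window_samples, "window_samples", lower = 1)
  check_number(cfg$stats$min_run, "min_run", lower = 1)
  if (!cfg$splits$median_tie %in% c("exclude", "slow")) {
    stop_config("splits$median_tie must be 'exclude' or 'slow'")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

SCHEMA_VERSION <- "1.0"
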