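# Shared fixtures, all built in code.

tiny_paradigm <- function(n_subjects = 1L, blocks = 2L, trials = 40L,
                          seed = 1L) {
  paradigm_config(n_subjects = n_subjects, blocks_per_task = blocks,
                  trials_per_block = trials, seed = seed)
}

# noise-free, fully deterministic generator settings
quiet_effects <- function(...) {
  effect_params(noise_white_sd = 0, noise_pink_sd = 0,
                early_amp_jitter_sd = 0, blink_rate = 0, rt_base_sd = 0,
                accuracy_rate = 1, ...)
}

flagged_trials <- function(config = tiny_paradigm(),
                           effects = quiet_effects(), seed = 1L) {
  filter_behavior(simulate_behavior(design_trials(config, seed), effects,
                                    seed = seed + 1L))
}

# minimal behavioural trial table for the filter / summary / split tests
toy_trials <- function(rt, correct = TRUE, task = "color",
                       trial_type = "PC", target_color = "red",
                       target_orientation = "left", probe_color = "red",
                       color_pair = "red-green", subject = 1L, block = 1L) {
  n <- length(rt)
  data.frame(subject = subject, task = task, block = block,
             block_in_task = 1L, trial = seq_len(n), uid = seq_len(n),
             onset_s = seq_len(n), color_pair = color_pair,
             target_color = rep_len(target_color, n),
             probe_color = rep_len(probe_color, n),
             target_orientation = rep_len(target_orientation, n),
             trial_type = rep_len(trial_type, n),
             repetition = "switch", rt_ms = rt,
             correct = rep_len(correct, n), stringsAsFactors = FALSE)
}

# hand-built epoch set on a regular grid
toy_epochs <- function(data, fs = 100, t0_frac = 0.25,
                       channels = paste0("ch", seq_len(dim(data)[2]))) {
  ns <- dim(data)[3]
  offs <- seq.int(-round(t0_frac * ns), length.out = ns)
  gfbascan:::new_epoch_set(data, offs * 1000 / fs, channels, fs,
                           trial_ids = seq_len(dim(data)[1]))
}

toy_waveform <- function(values, fs = 254.31, channels = "pooled",
                         label = list()) {
  values <- matrix(values, nrow = length(channels))
  gfbascan:::new_waveform(values, (seq_len(ncol(values)) - 1L) * 1000 / fs,
                          channels, fs, n_trials = 1L, label = label)
}

expect_all_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
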