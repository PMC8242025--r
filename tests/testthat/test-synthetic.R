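test_that("default design yields the expected trial counts and block order", {
  cfg <- paradigm_config(n_subjects = 1L)
  tr <- design_trials(cfg, seed = 1L)
  expect_equal(nrow(tr), 2160L)
  expect_equal(unname(table(tr$task)), c(1080L, 1080L), ignore_attr = TRUE)
  # expected per-type count per task: probe uniform over five colors
  expect_equal(cfg$blocks_per_task * cfg$trials_per_block / 5, 216)
  # empirical PC count within the binomial 99.9% band around 216
  n_pc <- sum(tr$trial_type == "PC" & tr$task == "color")
  band <- qbinom(c(5e-4, 1 - 5e-4), 1080L, 1 / 5)
  expect_gte(n_pc, band[1])
  expect_lte(n_pc, band[2])
  # pseudorandomization: pair never repeated, task changes every 2nd block
  blocks <- unique(tr[, c("block", "task", "color_pair")])
  blocks <- blocks[order(blocks$block), ]
  expect_true(all(blocks$color_pair[-1] != blocks$color_pair[-12]))
  expect_equal(rle(blocks$task)$lengths, rep(2L, 6L))
  # derived fields respect the trial-record rules
  pair_cols <- strsplit(blocks$color_pair[1], "-")[[1]]
  is_pc <- tr$probe_color == tr$target_color
  expect_equal(tr$trial_type == "PC", is_pc)
  expect_true(all(tr$trial_type[tr$probe_color == "magenta"] == "magenta"))
  first <- tr$trial == 1L
  expect_true(all(tr$repetition[first] == "undefined"))
  expect_false(any(tr$repetition[!first] == "undefined"))
  # onsets strictly increase within the session
  expect_true(all(diff(tr$onset_s) > 0))
})

test_that("zero blocks give an empty trial list and bad palettes error", {
  cfg <- paradigm_config(n_subjects = 1L, blocks_per_task = 0L)
  expect_equal(nrow(design_trials(cfg, 1L)), 0L)
  expect_error(paradigm_config(probe_colors = c("red", "green", "blue",
                                                "yellow", "red")),
               "distinct")
  expect_error(paradigm_config(probe_colors = c("red", "green", "blue",
                                                "pink", "magenta")),
               "target colors")
})

test_that("the design is deterministic and display-balanced", {
  cfg <- paradigm_config(n_subjects = 1L)
  tr <- design_trials(cfg, seed = 7L)
  expect_identical(tr, design_trials(cfg, seed = 7L))
  # each unique display within one task and pair: 3 blocks x 180 trials over
  # 20 displays, expected 27 occurrences, checked at the binomial 99% band
  color <- tr[tr$task == "color", ]
  for (pair in unique(color$color_pair)) {
    sub <- color[color$color_pair == pair, ]
    expect_equal(nrow(sub), 540L)
    counts <- table(paste(sub$target_color, sub$target_orientation,
                          sub$probe_color))
    expect_equal(540 / 20, 27)
    band <- qbinom(c(0.005, 0.995), 540L, 1 / 20)
    expect_true(all(counts >= band[1] & counts <= band[2]))
  }
})

test_that("trial-type proportions follow the probe-color distribution", {
  tr <- design_trials(paradigm_config(n_subjects = 2L), seed = 3L)
  n <- nrow(tr)
  probs <- c(PC = 1 / 5, DC = 1 / 5, nontarget = 2 / 5, magenta = 1 / 5)
  for (type in names(probs)) {
    band <- qbinom(c(5e-4, 1 - 5e-4), n, probs[[type]])
    expect_gte(sum(tr$trial_type == type), band[1])
    expect_lte(sum(tr$trial_type == type), band[2])
  }
  # repeat/switch tags equally frequent among defined trials
  def <- tr$repetition[tr$repetition != "undefined"]
  band <- qbinom(c(5e-4, 1 - 5e-4), length(def), 0.5)
  expect_gte(sum(def == "repeat"), band[1])
  expect_lte(sum(def == "repeat"), band[2])
})

test_that("degenerate behaviour generator gives constant reaction times", {
  eff <- quiet_effects(dc_rt_cost = 0, repetition_benefit = 0,
                       early_amp_rt_coupling = 0)
  tr <- simulate_behavior(design_trials(tiny_paradigm(), 1L), eff, seed = 2L)
  expect_true(all(tr$rt_ms == eff$rt_base_mean))
  expect_true(all(tr$correct))
  # deterministic given the seed
  eff2 <- effect_params()
  tr1 <- simulate_behavior(design_trials(tiny_paradigm(), 1L), eff2, seed = 5L)
  tr2 <- simulate_behavior(design_trials(tiny_paradigm(), 1L), eff2, seed = 5L)
  expect_identical(tr1, tr2)
})

test_that("the repetition benefit is recovered at Monte-Carlo scale", {
  cfg <- paradigm_config(n_subjects = 10L)
  eff <- effect_params(repetition_benefit = 40)
  tr <- simulate_behavior(design_trials(cfg, seed = 4L), eff, seed = 5L)
  def <- tr[tr$repetition != "undefined", ]
  d <- mean(def$rt_ms[def$repetition == "switch"]) -
    mean(def$rt_ms[def$repetition == "repeat"])
  se <- sqrt(var(def$rt_ms[def$repetition == "switch"]) /
               sum(def$repetition == "switch") +
               var(def$rt_ms[def$repetition == "repeat"]) /
               sum(def$repetition == "repeat"))
  expect_lt(abs(d - 40), 3 * se)
})

test_that("default behaviour meets the fast-and-accurate calibration", {
  tr <- filter_behavior(simulate_dataset(paradigm_config(), effect_params(),
                                         seed = 1L))
  sm <- summarize_behavior(tr)
  expect_equal(nrow(sm), 6L)
  expect_true(all(sm$mean_rt_ms < 410))
  expect_true(all(sm$accuracy_pct > 92))
})

test_that("noise-free epochs reproduce the injected condition deltas exactly", {
  cfg <- tiny_paradigm(trials = 80L)
  eff <- quiet_effects()
  tr <- flagged_trials(cfg, eff, seed = 2L)
  trc <- tr[tr$task == "color", ]
  ep <- baseline_correct(synthesize_epochs(trc, eff, cfg, seed = 3L))
  dw <- pool_channels(difference_wave(
    average_condition(ep, trc, "color", "DC"),
    average_condition(ep, trc, "color", "nontarget")))
  expect_equal(mean_amplitude(dw, eff$early_dc_window), eff$early_dc_amp,
               tolerance = 1e-12)
  expect_equal(mean_amplitude(dw, eff$late_pc_window), eff$late_dc_amp,
               tolerance = 1e-12)
  # with all amplitudes zero the three condition averages are identical
  eff0 <- quiet_effects(early_dc_amp = 0, late_pc_amp = 0, late_dc_amp = 0)
  tr0 <- flagged_trials(cfg, eff0, seed = 2L)
  trc0 <- tr0[tr0$task == "color", ]
  ep0 <- synthesize_epochs(trc0, eff0, cfg, seed = 3L)
  w <- lapply(c("PC", "DC", "nontarget"), function(ty) {
    average_condition(ep0, trc0, "color", ty)$data
  })
  expect_all_equal(w[[1]], w[[2]])
  expect_all_equal(w[[2]], w[[3]])
})

test_that("continuous recording and epoch generators agree where noise is off", {
  cfg <- tiny_paradigm(trials = 30L)
  eff <- quiet_effects()
  tr <- flagged_trials(cfg, eff, seed = 6L)
  trc <- tr[tr$task == "color", ]
  rec <- synthesize_recording(trc, eff, cfg, seed = 7L)
  ep_rec <- extract_epochs(rec, trc)
  ep_dir <- synthesize_epochs(trc, eff, cfg, seed = 7L,
                              channels = cfg$recording_channels)
  expect_equal(ep_rec$time_ms, ep_dir$time_ms)
  expect_all_equal(ep_rec$data, ep_dir$data, tol = 1e-9)
})

test_that("planted blinks are exactly the epochs the rejection flags", {
  cfg <- tiny_paradigm(trials = 30L)
  eff <- quiet_effects(blink_amp = 150)
  tr <- flagged_trials(cfg, eff, seed = 2L)
  trc <- tr[tr$task == "color", ]
  planted <- trc$uid[c(3L, 11L, 25L)]
  rec <- synthesize_recording(trc, eff, cfg, seed = 3L,
                              blink_trials = planted)
  ep <- extract_epochs(rec, trc)
  rej <- reject_artifacts(ep, threshold_uv = 100,
                          exclude_channels = unname(cfg$mastoid_channels))
  expect_setequal(rej$report$table$uid[rej$report$table$rejected], planted)
  expect_setequal(rej$epochs$trial_ids, setdiff(trc$uid, planted))
})

test_that("an effect window outside the epoch support raises a config error", {
  cfg <- tiny_paradigm(trials = 10L)
  expect_error(effect_params(early_dc_window = c(800, 900)), "interval")
  eff <- quiet_effects()
  tr <- flagged_trials(cfg, eff, seed = 1L)
  expect_error(synthesize_epochs(tr[tr$task == "color", ], eff, cfg,
                                 window_ms = c(-50, 60)),
               "outside the epoch support")
})
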