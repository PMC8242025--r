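make_cond_epochs <- function(values) {
  # one-channel epochs with constant per-trial values
  n <- length(values)
  data <- array(rep(values, 20), dim = c(n, 1, 20))
  toy_epochs(data, channels = "PO3")
}

test_that("condition averaging is the arithmetic mean over eligible trials", {
  ep <- make_cond_epochs(c(1, 3, 100))
  tr <- toy_trials(rt = c(300, 310, 320), trial_type = c("PC", "PC", "DC"))
  tr <- filter_behavior(tr)
  w <- average_condition(ep, tr, "color", "PC")
  expect_true(all(w$data == 2))
  expect_equal(w$n_trials, 2L)
  # single epoch: identity
  w1 <- average_condition(ep, tr, "color", "DC")
  expect_true(all(w1$data == 100))
  # empty cell errors with its name
  expect_error(average_condition(ep, tr, "orientation", "PC"),
               "task=orientation")
  # magenta probes are not an averaging target
  expect_error(average_condition(ep, tr, "color", "magenta"), "PC, DC")
  # ineligible trials never enter
  tr2 <- tr
  tr2$erp_eligible[2] <- FALSE
  expect_true(all(average_condition(ep, tr2, "color", "PC")$data == 1))
})

test_that("averaging is linear over disjoint trial sets", {
  set.seed(4)
  data <- array(rnorm(12 * 2 * 30), dim = c(12, 2, 30))
  ep <- toy_epochs(data, channels = c("PO3", "PO7"))
  w_a <- average_trials(ep, 1:4)
  w_b <- average_trials(ep, 5:12)
  w_all <- average_trials(ep, 1:12)
  expect_all_equal(w_all$data, (4 * w_a$data + 8 * w_b$data) / 12)
})

test_that("difference waves subtract sample-wise and antisymmetrize", {
  a <- toy_waveform(c(1, 2, 3), label = list(task = "color", trial_type = "DC"))
  b <- toy_waveform(c(0.5, 1, 4),
                    label = list(task = "color", trial_type = "nontarget"))
  d <- difference_wave(a, b)
  expect_equal(d$data[1, ], c(0.5, 1, -1))
  expect_equal(unname(d$n_trials), c(1, 1))
  expect_all_equal(difference_wave(a, a)$data, rep(0, 3))
  expect_all_equal(difference_wave(a, b)$data, -difference_wave(b, a)$data)
  short <- toy_waveform(c(1, 2))
  expect_error(difference_wave(a, short), "mismatch")
})

test_that("channel pooling averages the named channels", {
  w <- toy_waveform(rbind(c(2, 2), c(4, 6)), channels = c("PO3", "PO7"))
  p <- pool_channels(w)
  expect_equal(p$data[1, ], c(3, 4))
  expect_equal(p$channels, "pooled")
  same <- toy_waveform(rbind(c(1, 5), c(1, 5)), channels = c("PO3", "PO7"))
  expect_equal(pool_channels(same)$data[1, ], c(1, 5))
  expect_error(pool_channels(w, c("PO3", "PO9")), "PO9")
})

test_that("grand averaging is an unweighted mean across subjects", {
  w1 <- toy_waveform(c(1, 2), label = list(task = "color", trial_type = "PC"))
  w2 <- toy_waveform(c(3, 6), label = list(task = "color", trial_type = "PC"))
  w2$n_trials <- 50L                       # trial counts must not reweight
  g <- grand_average(list(w1, w2))
  expect_equal(g$data[1, ], c(2, 4))
  expect_equal(g$n_trials, 2L)
  expect_equal(grand_average(list(w1))$data, w1$data)
  w3 <- toy_waveform(c(0, 0), label = list(task = "color", trial_type = "DC"))
  expect_error(grand_average(list(w1, w3)), "mixed labels")
})

test_that("mean amplitude uses the left-closed right-open sample window", {
  cst <- toy_waveform(rep(4.2, 100))
  expect_equal(mean_amplitude(cst, c(73, 96)), 4.2)
  # linear ramp: grid-exact expectation computed by enumerating the grid
  fs <- 254.31
  t_ms <- (0:99) * 1000 / fs
  ramp <- toy_waveform(seq(0, 10, length.out = 100), fs = fs)
  idx <- which(t_ms >= 73 & t_ms < 96)
  expected <- mean(seq(0, 10, length.out = 100)[idx])
  expect_equal(mean_amplitude(ramp, c(73, 96)), expected)
  expect_gt(expected, 0)                     # sanity: mid-ramp value
  expect_error(mean_amplitude(cst, c(5000, 6000)), "no samples")
})

test_that("the display smoother halves a cutoff-frequency sinusoid", {
  fs <- 254.31
  n <- 2000L
  t_s <- (0:(n - 1)) / fs
  sine <- toy_waveform(sin(2 * pi * 23 * t_s), fs = fs)
  sm <- gaussian_lowpass(sine, 23)
  mid <- 200:1800
  atten <- sd(sm$data[1, mid]) / sd(sine$data[1, mid])
  expect_equal(atten, 0.5, tolerance = 0.02)
  expect_true(isTRUE(sm$label$display_only))
  # constant signals pass unchanged (unit DC gain)
  cst <- toy_waveform(rep(2.5, 300))
  expect_all_equal(gaussian_lowpass(cst)$data, rep(2.5, 300), tol = 1e-9)
  # mean preserved, max |amplitude| not increased for nonnegative input
  set.seed(5)
  x <- abs(rnorm(400))
  w <- toy_waveform(x, fs = fs)
  smw <- gaussian_lowpass(w)
  expect_equal(mean(smw$data), mean(x), tolerance = 5e-3)
  expect_lte(max(abs(smw$data)), max(abs(x)) + 1e-12)
})

test_that("the full noise-free chain reproduces injected deltas at every stage", {
  cfg <- tiny_paradigm(n_subjects = 2L, trials = 60L)
  eff <- quiet_effects()
  subj_wave <- function(s, type) {
    tr <- flagged_trials(cfg, eff, seed = 10L + s)
    tr_s <- tr[tr$subject == s & tr$task == "color", ]
    ep <- baseline_correct(synthesize_epochs(tr_s, eff, cfg, seed = 20L + s))
    pool_channels(average_condition(ep, tr_s, "color", type))
  }
  gw <- function(type) {
    grand_average(lapply(1:2, subj_wave, type = type))
  }
  dw <- difference_wave(gw("DC"), gw("nontarget"))
  expect_equal(mean_amplitude(dw, eff$early_dc_window), eff$early_dc_amp,
               tolerance = 1e-12)
  dpc <- difference_wave(gw("PC"), gw("nontarget"))
  expect_equal(mean_amplitude(dpc, eff$late_pc_window), eff$late_pc_amp,
               tolerance = 1e-12)
  expect_equal(mean_amplitude(dpc, eff$early_dc_window), 0, tolerance = 1e-12)
})
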