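test_that("behavioural filter applies the strict 200/1300 ms bounds", {
  tr <- toy_trials(rt = c(150, 250, 1400, 300),
                   correct = c(TRUE, TRUE, TRUE, FALSE))
  fl <- filter_behavior(tr)
  expect_equal(fl$anticipatory, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$delayed, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(fl$incorrect, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(which(fl$erp_eligible), 2L)
  # boundary values 200 and 1300 are kept (strict inequalities)
  fl2 <- filter_behavior(toy_trials(rt = c(200, 1300)))
  expect_true(all(fl2$erp_eligible))
  # missing RT flagged invalid
  fl3 <- filter_behavior(toy_trials(rt = c(NA, 400)))
  expect_equal(fl3$invalid_rt, c(TRUE, FALSE))
  expect_equal(fl3$erp_eligible, c(FALSE, TRUE))
})

test_that("behavioural summary matches hand computation on a toy table", {
  tr <- rbind(toy_trials(rt = c(300, 350, 500), correct = c(TRUE, TRUE, FALSE),
                         trial_type = "PC"),
              toy_trials(rt = c(400, 420), trial_type = "DC"),
              toy_trials(rt = 380, trial_type = "nontarget"))
  tr$uid <- seq_len(nrow(tr))
  sm <- summarize_behavior(filter_behavior(tr))
  get <- function(ty, col) sm[sm$trial_type == ty & sm$task == "color", col]
  expect_equal(get("PC", "accuracy_pct"), 100 * 2 / 3)
  expect_equal(get("PC", "mean_rt_ms"), 325)      # correct trials only
  expect_equal(get("DC", "mean_rt_ms"), 410)
  expect_equal(get("DC", "accuracy_pct"), 100)
  expect_equal(get("nontarget", "n_valid"), 1L)
  # the frame always spans the 2 x 3 analysis cells for two-task data
  tr2 <- rbind(tr, toy_trials(rt = 390, task = "orientation"))
  tr2$uid <- seq_len(nrow(tr2))
  sm2 <- summarize_behavior(filter_behavior(tr2))
  expect_equal(nrow(sm2), 6L)
  # empty cells are NA, not zero
  expect_true(is.na(sm2$mean_rt_ms[sm2$task == "orientation" &
                                     sm2$trial_type == "DC"]))
})

test_that("mastoid re-referencing implements the linked-mastoid transform", {
  ch <- c("PO3", "PO7", "M1", "M2")
  rec <- structure(list(data = matrix(0, 4, 10,
                                      dimnames = list(ch, NULL)),
                        channels = ch, sampling_rate = 100,
                        events = data.frame(sample = integer(0),
                                            uid = integer(0))),
                   class = "continuous_recording")
  # left mastoid identically zero: nothing changes
  rec$data["PO3", ] <- 5
  expect_equal(rereference(rec)$data, rec$data)
  # constant 2 uV left mastoid shifts every channel by -1 uV
  rec$data["M1", ] <- 2
  shifted <- rereference(rec)
  expect_true(all(shifted$data["PO3", ] == 4))
  expect_true(all(shifted$data["PO7", ] == -1))
  expect_true(all(shifted$data["M1", ] == 1))
  # algebraic check: with a right-mastoid online reference the transform
  # re-references to the mastoid average
  set.seed(1)
  v <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(ch, NULL))  # true potentials
  recorded <- sweep(v, 2L, v["M2", ], "-")
  rec$data <- recorded
  out <- rereference(rec)$data
  expected <- sweep(v, 2L, (v["M1", ] + v["M2", ]) / 2, "-")
  expect_all_equal(out, expected)
  expect_error(rereference(rec, mastoid_left = "M9"), "M9")
})

test_that("epoching yields 229 samples at 254.31 Hz and drops edge events", {
  fs <- 254.31
  offs <- gfbascan:::epoch_sample_offsets(c(-200, 700), fs)
  expect_length(offs, 229L)
  # enumeration of the time grid: all samples with -200 <= t < 700
  t_all <- (-1000:1000) * 1000 / fs
  expect_equal(sum(t_all >= -200 & t_all < 700), 229L)
  ch <- c("PO3", "M1")
  rec <- structure(list(data = matrix(rnorm(2 * 600), 2, 600,
                                      dimnames = list(ch, NULL)),
                        channels = ch, sampling_rate = fs,
                        events = data.frame(sample = c(0L, 300L),
                                            uid = c(1L, 2L))),
                   class = "continuous_recording")
  trials <- data.frame(uid = c(1L, 2L))
  expect_warning(ep <- extract_epochs(rec, trials), "dropped")
  expect_equal(ep$trial_ids, 2L)
  expect_equal(dim(ep$data), c(1L, 2L, 229L))
  # uniform grid with the onset sample at exactly 0 ms
  expect_all_equal(diff(ep$time_ms), rep(1000 / fs, 228L))
  expect_equal(sum(ep$time_ms == 0), 1L)
  # epoch content equals the raw slice
  expect_equal(ep$data[1, 1, ], rec$data["PO3", 300L + offs + 1L])
})

test_that("peak-to-peak rejection is exact, idempotent and monotone", {
  data <- array(0, dim = c(3, 2, 50))
  data[2, 1, 25] <- 120                       # 120 uV transient on channel 1
  ep <- toy_epochs(data, channels = c("PO3", "PO7"))
  res100 <- reject_artifacts(ep, 100, exclude_channels = character(0))
  expect_equal(res100$epochs$trial_ids, c(1L, 3L))
  expect_equal(res100$report$fraction, 1 / 3)
  res130 <- reject_artifacts(ep, 130, exclude_channels = character(0))
  expect_equal(res130$epochs$trial_ids, 1:3)   # kept at the laxer threshold
  # all-flat epochs are never rejected
  flat <- toy_epochs(array(0, dim = c(4, 1, 20)), channels = "PO3")
  expect_equal(reject_artifacts(flat, 70)$report$fraction, 0)
  expect_error(reject_artifacts(ep, 0), "> 0")
  # idempotence and threshold monotonicity on noisy epochs
  set.seed(2)
  noisy <- toy_epochs(array(rnorm(60 * 2 * 40, sd = 18), dim = c(60, 2, 40)),
                      channels = c("PO3", "PO7"))
  once <- reject_artifacts(noisy, 100, exclude_channels = character(0))
  twice <- reject_artifacts(once$epochs, 100, exclude_channels = character(0))
  expect_equal(twice$epochs$trial_ids, once$epochs$trial_ids)
  expect_equal(twice$report$fraction, 0)
  for (pair in list(c(70, 90), c(90, 115))) {
    k1 <- reject_artifacts(noisy, pair[1], exclude_channels = character(0))
    k2 <- reject_artifacts(noisy, pair[2], exclude_channels = character(0))
    expect_true(all(k1$epochs$trial_ids %in% k2$epochs$trial_ids))
  }
})

test_that("baseline correction zeroes the prestimulus mean and commutes with averaging", {
  set.seed(3)
  data <- array(rnorm(10 * 2 * 80), dim = c(10, 2, 80)) + 5
  ep <- toy_epochs(data, fs = 100, channels = c("PO3", "PO7"))
  bl <- baseline_correct(ep, c(-150, 0))
  idx <- which(ep$time_ms >= -150 & ep$time_ms < 0)
  expect_lt(max(abs(apply(bl$data[, , idx], c(1, 2), mean))), 1e-9)
  expect_true(bl$baseline_applied)
  # constant offset is removed entirely
  cst <- toy_epochs(array(5, dim = c(2, 1, 40)), channels = "PO3")
  expect_all_equal(baseline_correct(cst, c(-80, 0))$data,
                   array(0, dim = c(2, 1, 40)))
  # zero-mean baseline leaves the data untouched
  zm <- data - as.vector(apply(data[, , idx, drop = FALSE], c(1, 2), mean))
  ep_zm <- toy_epochs(zm, fs = 100, channels = c("PO3", "PO7"))
  expect_all_equal(baseline_correct(ep_zm, c(-150, 0))$data, zm)
  # correct-then-average equals average-then-correct
  avg_then <- apply(bl$data, c(2, 3), mean)
  raw_avg <- apply(ep$data, c(2, 3), mean)
  then_avg <- raw_avg - rowMeans(raw_avg[, idx, drop = FALSE])
  expect_all_equal(avg_then, then_avg)
  expect_error(baseline_correct(ep, c(-5000, -4000)), "baseline")
})
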