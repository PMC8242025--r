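aov_oracle <- function(y, a, b) {
  n <- nrow(y)
  dat <- data.frame(y = as.vector(t(y)),
                    s = factor(rep(seq_len(n), each = a * b)),
                    A = factor(rep(rep(seq_len(a), each = b), n)),
                    B = factor(rep(rep(seq_len(b), a), n)))
  fit <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = dat))
  c(fit[["Error: s:A"]][[1]]["A", "F value"],
    fit[["Error: s:B"]][[1]]["B", "F value"],
    fit[["Error: s:A:B"]][[1]]["A:B", "F value"])
}

test_that("corrected alpha follows the stated formula and is monotone", {
  expect_equal(round(corrected_alpha(0.05, 50, 254.31), 4), 0.02)
  expect_equal(corrected_alpha(0.05, 254.31 / 2, 254.31), 0.05)
  expect_equal(corrected_alpha(0.05, 0, 254.31), 0)
  # closed form at an arbitrary point
  expect_equal(corrected_alpha(0.1, 30, 200), 1 - 0.9^(60 / 200))
  # strictly increasing in fc and alpha0
  fcs <- seq(5, 120, by = 5)
  expect_true(all(diff(sapply(fcs, corrected_alpha, alpha0 = 0.05,
                              fs = 254.31)) > 0))
  alphas <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(sapply(alphas, corrected_alpha, fc = 50,
                              fs = 254.31)) > 0))
  expect_error(corrected_alpha(0.05, 200, 254.31), "fc")
  expect_error(corrected_alpha(1.5, 50, 254.31), "alpha0")
})

test_that("paired t matches the closed form and handles degeneracy", {
  res <- paired_t(c(1, 2, 6), c(2, 2, 3))
  expect_equal(round(res$t, 4), 0.5547)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 2 * pt(-abs(res$t), 2))
  same <- paired_t(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- paired_t(c(2, 3, 4), c(1, 2, 3))    # constant nonzero difference
  expect_true(const$degenerate)
  expect_equal(const$p, 0)
  expect_error(paired_t(1, 2), "two pairs")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("rm_anova agrees with the aov oracle on random small designs", {
  set.seed(11)
  worst <- 0
  for (k in 1:50) {
    a <- sample(2:4, 1)
    b <- sample(2:3, 1)
    n <- sample(4:9, 1)
    y <- matrix(rnorm(n * a * b, sd = rep(runif(a * b, 0.5, 2), each = n)),
                n, a * b) + rnorm(n)
    res <- rm_anova(y, a, b)
    worst <- max(worst, abs(res$F - aov_oracle(y, a, b)))
    expect_equal(res$df1, c(a - 1L, b - 1L, (a - 1L) * (b - 1L)))
    expect_equal(res$df2, res$df1 * (n - 1L))
    expect_true(all(res$epsilon >= 1 / res$df1 - 1e-12 & res$epsilon <= 1))
    expect_equal(res$p, pf(res$F, res$df1, res$df2, lower.tail = FALSE))
  }
  expect_lt(worst, 1e-6)
})

test_that("two-level effects reduce to the squared paired t with epsilon one", {
  set.seed(12)
  y <- matrix(rnorm(22 * 6), 22, 6) + rnorm(22)
  res <- rm_anova(y, 2, 3, c("TASK", "COLOR"))
  # factor A has 2 levels: F equals the square of the paired t on the
  # subject-level marginal means and epsilon is exactly 1
  m1 <- rowMeans(y[, 1:3])
  m2 <- rowMeans(y[, 4:6])
  tt <- paired_t(m1, m2)
  expect_equal(res$F[1], tt$t^2, tolerance = 1e-10)
  expect_equal(res$p[1], tt$p, tolerance = 1e-10)
  expect_equal(res$epsilon[1], 1)
  y4 <- matrix(rnorm(10 * 4), 10, 4)
  expect_true(all(rm_anova(y4, 2, 2)$epsilon == 1))
})

test_that("greenhouse-geisser epsilon matches an eigenvalue oracle and caps p", {
  set.seed(13)
  # strongly nonspherical scores: shared component inflates one direction
  base <- rnorm(30)
  y <- cbind(base + rnorm(30, sd = 0.1), base + rnorm(30, sd = 0.1),
             rnorm(30, sd = 3))
  y <- cbind(y, y + rnorm(30, sd = 0.5))     # 2 x 3 design
  res <- rm_anova(y, 2, 3, c("A", "B"))
  C <- gfbascan:::orth_contrasts(3)
  Cfull <- matrix(1 / sqrt(2), 1, 2) %x% C
  M <- stats::cov(y %*% t(Cfull))
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  eps_oracle <- sum(lam)^2 / (2 * sum(lam^2))
  expect_equal(res$epsilon[2], eps_oracle, tolerance = 1e-10)
  expect_lt(res$epsilon[2], 0.9)             # nonsphericity was injected
  # the correction can only raise significant p-values
  sig <- res[res$F > 1, ]
  expect_true(all(sig$p_gg >= sig$p - 1e-12))
})

test_that("degenerate cell tables yield zero F", {
  y <- matrix(rep(c(1, 2, 3, 4, 5), each = 6), 5, 6, byrow = TRUE)
  res <- rm_anova(y, 2, 3)                   # cells equal within subject
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  expect_error(rm_anova(y[1, , drop = FALSE], 2, 3), "two subjects")
  y_na <- y
  y_na[2, 3] <- NA
  expect_error(rm_anova(y_na, 2, 3), "missing")
})

test_that("onset detection needs five or more successive sub-alpha samples", {
  expect_equal(nrow(detect_onsets(rep(0.5, 40), 0.02)), 0L)
  p <- rep(0.5, 40)
  p[10:14] <- 0.001
  runs <- detect_onsets(p, 0.02)
  expect_equal(runs$onset, 10L)
  expect_equal(runs$length, 5L)
  p4 <- rep(0.5, 40)
  p4[10:13] <- 0.001                         # only four in a row
  expect_equal(nrow(detect_onsets(p4, 0.02)), 0L)
  # maximal runs, multiple intervals
  p2 <- rep(1, 60)
  p2[5:12] <- 0.01
  p2[30:36] <- 0.01
  runs2 <- detect_onsets(p2, 0.02, min_run = 5)
  expect_equal(runs2$onset, c(5L, 30L))
  expect_equal(runs2$offset, c(12L, 36L))
})

test_that("onset detection ignores the values of non-significant samples", {
  set.seed(14)
  for (k in 1:20) {
    p <- runif(60)
    alpha <- 0.3
    ref <- detect_onsets(p, alpha)
    q <- p
    above <- q >= alpha
    q[above] <- runif(sum(above), alpha, 1)  # reshuffle non-significant values
    expect_identical(detect_onsets(q, alpha), ref)
  }
})

test_that("the sliding rANOVA recovers an injected interaction window", {
  fs <- 254.31
  offs <- gfbascan:::epoch_sample_offsets(c(-200, 700), fs)
  t_ms <- offs * 1000 / fs
  ns <- length(t_ms)
  n_subj <- 22L
  set.seed(15)
  cells <- array(rnorm(n_subj * 6 * ns, sd = 0.02), dim = c(n_subj, 6, ns))
  box <- t_ms >= 100 & t_ms < 150
  cells[, 2, box] <- cells[, 2, box] - 1     # color-task DC cell only
  scan <- suppressMessages(sliding_anova(cells, t_ms))
  iv <- scan$intervals[["TASK:COLOR"]]
  expect_equal(nrow(iv), 1L)
  win_ms <- 3 * 1000 / fs
  expect_lt(abs(iv$onset_ms - 100), win_ms + 1e-9)
  expect_lt(abs(iv$offset_ms + win_ms - 150), win_ms + 1e-9)
  # identical condition waveforms for every subject: nothing detected
  flat <- array(rep(rnorm(ns, sd = 0.1), each = n_subj * 6),
                dim = c(n_subj, 6, ns))
  scan0 <- suppressMessages(sliding_anova(flat, t_ms))
  expect_true(all(vapply(scan0$intervals, nrow, 1L) == 0L))
  # the window is three samples, i.e. 11.8 ms at this sampling rate
  expect_equal(round(scan$window_samples * 1000 / fs, 1), 11.8)
})

test_that("the sliding paired t mirrors the ANOVA scan conventions", {
  fs <- 254.31
  t_ms <- (0:100) * 1000 / fs
  n_subj <- 12L
  set.seed(16)
  pairs <- array(rnorm(n_subj * 2 * 101, sd = 0.05),
                 dim = c(n_subj, 2, 101))
  scan0 <- suppressMessages(sliding_t(pairs, t_ms, range_ms = c(0, 300)))
  expect_equal(nrow(scan0$intervals$t), 0L)
  box <- t_ms >= 120 & t_ms < 180
  pairs[, 1, box] <- pairs[, 1, box] - 1
  scan1 <- suppressMessages(sliding_t(pairs, t_ms, range_ms = c(0, 300)))
  iv <- scan1$intervals$t
  expect_gte(nrow(iv), 1L)
  expect_lte(iv$onset_ms[1], 130)
  expect_gte(iv$offset_ms[nrow(iv)], 150)
  expect_equal(scan1$alpha, 0.05)            # explorative scans stay at 0.05
})

test_that("the split interaction ANOVA separates additive from crossover data", {
  set.seed(17)
  n <- 22L
  subj <- rnorm(n)
  # additive: row + column effects only
  additive <- cbind(subj + 0 + 0, subj + 0 + 1, subj + 2 + 0, subj + 2 + 1) +
    rnorm(4 * n, sd = 0.05)
  res_add <- split_interaction_anova(additive)
  expect_lt(res_add$F[3], qf(0.999, 1, n - 1))
  expect_true(all(res_add$epsilon == 1))     # 2 x 2: epsilon is exactly 1
  # crossover at generator-like magnitudes: early effect in fast only,
  # late effect in slow only
  crossover <- cbind(subj - 1.1, subj - 0.55, subj - 0.4, subj - 0.9) +
    rnorm(4 * n, sd = 0.3)
  res_x <- split_interaction_anova(crossover)
  expect_lt(res_x$p_gg[3], 0.05)
  expect_equal(res_x$effect[3], "EARLYLATE:FASTSLOW")
})
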