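# Within-subject factorial ANOVA with Greenhouse-Geisser correction, paired
# t-tests, the sampling-rate-aware corrected alpha, sliding-window scans and
# the consecutive-samples onset rule.  Implemented from first principles.

#' Corrected per-sample alpha for sliding-window tests
#'
#' `1 - (1 - alpha0)^(2 fc / fs)`: the per-test level that accounts for the
#' effective number of independent samples given the acquisition low-pass
#' filter `fc` and the sampling rate `fs`.  With alpha0 = 0.05, fc = 50 Hz
#' and fs = 254.31 Hz this is approximately 0.02.
#'
#' @param alpha0 nominal alpha in (0, 1).
#' @param fc low-pass filter cutoff in Hz, `0 <= fc <= fs/2`.
#' @param fs sampling rate in Hz (> 0).
#' @return The corrected alpha.
#' @export
corrected_alpha <- function(alpha0 = 0.05, fc = 50, fs = 254.31) {
  check_number(alpha0, "alpha0", lower = 1e-12, upper = 1 - 1e-12)
  check_number(fs, "fs", lower = 1e-12)
  check_number(fc, "fc", lower = 0, upper = fs / 2)
  1 - (1 - alpha0)^(2 * fc / fs)
}

# Orthonormal between-level contrasts: (k-1) x k matrix with orthonormal
# rows, each orthogonal to the constant vector.
orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)            # k x (k-1)
  C <- sweep(C, 2L, sqrt(colSums(C^2)), "/")
  t(C)
}

# Greenhouse-Geisser epsilon from the covariance of contrast scores.
# y: subjects x cells matrix; C: orthonormal effect contrasts on the cells.
gg_epsilon <- function(y, C) {
  q <- nrow(C)
  if (q <= 1L) return(1)
  Z <- y %*% t(C)
  M <- stats::cov(Z)
  tr <- sum(diag(M))
  tr2 <- sum(M * M)
  if (!is.finite(tr2) || tr2 <= 1e-300) return(1)
  min(1, max(1 / q, tr^2 / (q * tr2)))
}

#' Two-way within-subject (repeated-measures) ANOVA
#'
#' Complete balanced two-factor within-subject decomposition: each effect
#' (factor A, factor B, their interaction) is tested against its own
#' subject-by-effect error term.  The Greenhouse-Geisser epsilon of each
#' effect is the classical estimator from the covariance of the
#' orthonormalized within-subject contrast scores, and the corrected
#' p-value uses the epsilon-scaled degrees of freedom.
#'
#' @param y numeric matrix, subjects x cells, with cells ordered factor-A
#'   major (B varying fastest within each A level), no missing values.
#' @param levels_a,levels_b number of levels of the two factors (>= 2).
#' @param factor_names names of the two factors used in the output.
#' @return A `data.frame` of class `anova_rm` with one row per effect:
#'   effect, df1, df2, F, epsilon, p (uncorrected), p_gg.
#' @export
rm_anova <- function(y, levels_a, levels_b,
                     factor_names = c("A", "B")) {
  y <- as.matrix(y)
  a <- as.integer(levels_a)
  b <- as.integer(levels_b)
  n <- nrow(y)
  if (a < 2L || b < 2L) stop_config("both factors need at least two levels")
  if (n < 2L) stop_config("at least two subjects are required")
  if (ncol(y) != a * b) stop_config("'y' must have levels_a * levels_b columns")
  if (anyNA(y)) stop_config("missing cells are not supported (no imputation)")

  idxA <- rep(seq_len(a), each = b)
  idxB <- rep(seq_len(b), times = a)
  G <- mean(y)
  S <- rowMeans(y)                                        # subject means
  AS <- sapply(seq_len(a), function(i) rowMeans(y[, idxA == i, drop = FALSE]))
  BS <- sapply(seq_len(b), function(j) rowMeans(y[, idxB == j, drop = FALSE]))
  AS <- matrix(AS, n, a)
  BS <- matrix(BS, n, b)
  Am <- colMeans(AS)
  Bm <- colMeans(BS)
  cell <- colMeans(y)                                     # length a*b

  ss_A <- n * b * sum((Am - G)^2)
  ss_B <- n * a * sum((Bm - G)^2)
  ss_S <- a * b * sum((S - G)^2)
  ss_AB <- n * sum((cell - Am[idxA] - Bm[idxB] + G)^2)
  ss_AS <- b * sum((AS - outer(S, rep(1, a)) -
                      outer(rep(1, n), Am) + G)^2)
  ss_BS <- a * sum((BS - outer(S, rep(1, b)) -
                      outer(rep(1, n), Bm) + G)^2)
  ss_tot <- sum((y - G)^2)
  ss_ABS <- max(0, ss_tot - ss_A - ss_B - ss_S - ss_AB - ss_AS - ss_BS)

  CA <- orth_contrasts(a)
  CB <- orth_contrasts(b)
  onesA <- matrix(1 / sqrt(a), 1L, a)
  onesB <- matrix(1 / sqrt(b), 1L, b)
  eff <- list(
    list(name = factor_names[1], ss = ss_A, ss_err = ss_AS,
         df1 = a - 1L, C = CA %x% onesB),
    list(name = factor_names[2], ss = ss_B, ss_err = ss_BS,
         df1 = b - 1L, C = onesA %x% CB),
    list(name = paste(factor_names, collapse = ":"),
         ss = ss_AB, ss_err = ss_ABS,
         df1 = (a - 1L) * (b - 1L), C = CA %x% CB))

  rows <- lapply(eff, function(e) {
    df1 <- e$df1
    df2 <- df1 * (n - 1L)
    tol <- 1e-12 * max(1, ss_tot)
    if (e$ss_err <= tol) {
      f <- if (e$ss <= tol) 0 else Inf
    } else {
      f <- (e$ss / df1) / (e$ss_err / df2)
    }
    eps <- gg_epsilon(y, e$C)
    p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
    p_gg <- if (is.infinite(f)) 0 else {
      stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    }
    if (f == 0) p <- p_gg <- 1
    data.frame(effect = e$name, df1 = df1, df2 = df2, F = f,
               epsilon = eps, p = p, p_gg = p_gg)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("anova_rm", "data.frame")
  out
}

#' @export
print.anova_rm <- function(x, ...) {
  y <- as.data.frame(x)
  y$F <- signif(y$F, 5)
  y$epsilon <- round(y$epsilon, 4)
  y$p <- signif(y$p, 4)
  y$p_gg <- signif(y$p_gg, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Paired Student's t-test
#'
#' Closed-form paired t on per-subject values with explicit handling of the
#' degenerate zero-variance case: a constant nonzero difference gives
#' `p = 0` with `degenerate = TRUE`; all-zero differences give `t = 0`,
#' `p = 1`.
#'
#' @param a,b numeric vectors of per-subject values, equal length >= 2.
#' @return A list with `t`, `df`, `p` (two-sided), `mean_diff` and
#'   `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop_config("'a' and 'b' must have equal length")
  n <- length(a)
  if (n < 2L) stop_config("at least two pairs are required")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s <= 1e-300) {
    if (abs(m) <= 1e-300) {
      return(list(t = 0, df = df, p = 1, mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = sign(m) * Inf, df = df, p = 0, mean_diff = m,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = m,
       degenerate = FALSE)
}

#' Detect onsets as runs of consecutive sub-alpha samples
#'
#' Returns the maximal runs of consecutive samples with `p < alpha` of
#' length at least `min_run` (default: five or more successive samples).
#' The onset is the first sample of its run.  Samples with `p >= alpha`
#' (or missing p) never influence the result.
#'
#' @param pvals numeric vector of per-sample p-values.
#' @param alpha significance threshold.
#' @param min_run minimum run length.
#' @return `data.frame` with columns onset, offset (1-based indices into
#'   `pvals`) and length; zero rows when nothing is detected.
#' @export
detect_onsets <- function(pvals, alpha, min_run = 5L) {
  sig <- !is.na(pvals) & pvals < alpha
  if (!any(sig)) {
    return(data.frame(onset = integer(0), offset = integer(0),
                      length = integer(0)))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(onset = starts[keep], offset = ends[keep],
             length = r$lengths[keep])
}

# Shared window machinery: left-aligned (or centered) sliding windows of
# `window_samples` samples over the tested range; the tested value per
# subject and cell is the mean amplitude within the window.
sliding_windows <- function(time_ms, range_ms, window_samples,
                            align = c("left", "center")) {
  align <- match.arg(align)
  in_range <- which(time_ms >= range_ms[1] - 1e-9 & time_ms <= range_ms[2] + 1e-9)
  if (length(in_range) == 0L) stop_config("tested range contains no samples")
  shift <- if (align == "left") 0L else as.integer(window_samples %/% 2L)
  starts <- in_range - shift
  ok <- starts >= 1L & (starts + window_samples - 1L) <= length(time_ms) &
    (starts + window_samples - 1L) <= max(in_range)
  if (any(!ok)) {
    message(sum(!ok), " trailing/leading window position(s) outside the ",
            "tested range were skipped")
  }
  list(anchor = in_range[ok], start = starts[ok])
}

new_sliding_result <- function(effects_p, intervals, time_ms, anchor, start,
                               window_samples, alpha, range_ms) {
  structure(list(p = effects_p, intervals = intervals,
                 anchor_idx = anchor, anchor_ms = time_ms[anchor],
                 window_start_idx = start, window_samples = window_samples,
                 alpha = alpha, range_ms = range_ms, time_ms = time_ms),
            class = "sliding_result")
}

#' @export
print.sliding_result <- function(x, ...) {
  cat("<sliding_result> ", length(x$anchor_idx), " windows of ",
      x$window_samples, " samples over [", x$range_ms[1], ", ",
      x$range_ms[2], "] ms, alpha = ", signif(x$alpha, 3), "\n", sep = "")
  for (e in names(x$intervals)) {
    iv <- x$intervals[[e]]
    if (nrow(iv) == 0L) {
      cat("  ", e, ": no significant interval\n", sep = "")
    } else {
      cat("  ", e, ": ", paste(sprintf("%.1f-%.1f ms", iv$onset_ms,
                                       iv$offset_ms), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

intervals_ms <- function(runs, anchor_ms, anchor_idx) {
  if (nrow(runs) == 0L) {
    return(data.frame(onset = integer(0), offset = integer(0),
                      length = integer(0), onset_ms = numeric(0),
                      offset_ms = numeric(0)))
  }
  runs$onset_ms <- anchor_ms[runs$onset]
  runs$offset_ms <- anchor_ms[runs$offset]
  runs$onset_idx <- anchor_idx[runs$onset]
  runs$offset_idx <- anchor_idx[runs$offset]
  runs
}

#' Sliding-window two-way repeated-measures ANOVA
#'
#' Time-sample-by-time-sample scan of the 2 (task) x 3 (probe color) design:
#' for each tested sample, each subject's cell value is the mean amplitude
#' over a short window (default three samples, 11.8 ms at 254.31 Hz) and a
#' within-subject [rm_anova()] is run.  Detected intervals per effect are
#' maximal runs of at least `min_run` consecutive sub-alpha samples at the
#' corrected alpha (see [corrected_alpha()]).
#'
#' @param cells array subjects x cells x samples of pooled-channel condition
#'   values, cells ordered factor-A major (B fastest).
#' @param time_ms sample times in ms.
#' @param levels_a,levels_b factor level counts (default 2 x 3).
#' @param factor_names factor names (default TASK, COLOR).
#' @param range_ms tested time range (default 0--300 ms).
#' @param window_samples window width in samples.
#' @param alpha per-sample alpha; when `NULL` it is derived via
#'   [corrected_alpha()] from `alpha0`, `fc` and the sampling rate implied
#'   by `time_ms`.
#' @param alpha0,fc inputs to [corrected_alpha()].
#' @param use_gg use Greenhouse-Geisser corrected p-values (default TRUE).
#' @param min_run minimum consecutive sub-alpha samples for an interval.
#' @param align window alignment on the tested sample: `left` (window
#'   starts at the sample) or `center`.
#' @return A `sliding_result`: per-sample p-values per effect, detected
#'   intervals, and the scan parameters.
#' @export
sliding_anova <- function(cells, time_ms, levels_a = 2L, levels_b = 3L,
                          factor_names = c("TASK", "COLOR"),
                          range_ms = c(0, 300), window_samples = 3L,
                          alpha = NULL, alpha0 = 0.05, fc = 50,
                          use_gg = TRUE, min_run = 5L,
                          align = c("left", "center")) {
  stopifnot(length(dim(cells)) == 3L, dim(cells)[2] == levels_a * levels_b)
  fs <- 1000 / stats::median(diff(time_ms))
  if (is.null(alpha)) alpha <- corrected_alpha(alpha0, fc, fs)
  win <- sliding_windows(time_ms, range_ms, window_samples, align)
  n_win <- length(win$anchor)
  effect_names <- c(factor_names, paste(factor_names, collapse = ":"))
  p <- matrix(NA_real_, n_win, 3L, dimnames = list(NULL, effect_names))
  for (k in seq_len(n_win)) {
    sl <- win$start[k]:(win$start[k] + window_samples - 1L)
    vals <- apply(cells[, , sl, drop = FALSE], c(1L, 2L), mean)
    res <- rm_anova(vals, levels_a, levels_b, factor_names)
    p[k, ] <- if (use_gg) res$p_gg else res$p
  }
  intervals <- lapply(effect_names, function(e) {
    intervals_ms(detect_onsets(p[, e], alpha, min_run), time_ms[win$anchor],
                 win$anchor)
  })
  names(intervals) <- effect_names
  new_sliding_result(p, intervals, time_ms, win$anchor, win$start,
                     window_samples, alpha, range_ms)
}

#' Sliding-window paired t-test
#'
#' Explorative sample-by-sample paired t between two conditions with the
#' same window-mean aggregation as [sliding_anova()]; by default the
#' uncorrected alpha 0.05 is used.
#'
#' @param pairs array subjects x 2 x samples.
#' @param time_ms sample times in ms.
#' @inheritParams sliding_anova
#' @return A `sliding_result` with a single `t` effect.
#' @export
sliding_t <- function(pairs, time_ms, range_ms = c(0, 300),
                      window_samples = 3L, alpha = 0.05, min_run = 5L,
                      align = c("left", "center")) {
  stopifnot(length(dim(pairs)) == 3L, dim(pairs)[2] == 2L)
  win <- sliding_windows(time_ms, range_ms, window_samples, align)
  n_win <- length(win$anchor)
  p <- matrix(NA_real_, n_win, 1L, dimnames = list(NULL, "t"))
  for (k in seq_len(n_win)) {
    sl <- win$start[k]:(win$start[k] + window_samples - 1L)
    vals <- apply(pairs[, , sl, drop = FALSE], c(1L, 2L), mean)
    p[k, 1L] <- paired_t(vals[, 1L], vals[, 2L])$p
  }
  intervals <- list(t = intervals_ms(detect_onsets(p[, 1L], alpha, min_run),
                                     time_ms[win$anchor], win$anchor))
  new_sliding_result(p, intervals, time_ms, win$anchor, win$start,
                     window_samples, alpha, range_ms)
}

#' 2 x 2 ANOVA on split ERP amplitudes
#'
#' Within-subject ANOVA with factors EARLYLATE (early vs late window GFBA
#' amplitude) and FASTSLOW (fast vs slow median-split responses), the test
#' used to establish the crossover between early and late distractor-color
#' modulation.
#'
#' @param amplitudes matrix subjects x 4, columns ordered (early.fast,
#'   early.slow, late.fast, late.slow).
#' @return An `anova_rm` table.
#' @export
split_interaction_anova <- function(amplitudes) {
  rm_anova(amplitudes, 2L, 2L, factor_names = c("EARLYLATE", "FASTSLOW"))
}
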