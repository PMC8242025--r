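# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never clobber a user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Expand one global seed into reproducible per-subject / per-stage substreams.
# Plain LCG mixing; keeps results in (0, 2^31 - 2] so set.seed() accepts them.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  x <- as.double(as.integer(seed) %% 2147483647L)
  for (k in ks) {
    x <- (x * 69069 + abs(as.double(k)) * 9973 + 12345) %% 2147483629
  }
  as.integer(x %% 2147483628) + 1L
}

# Configuration errors (exit code 2 at the CLI) vs data/artifact errors
# (exit code 3); both are ordinary errors with an extra condition class.
stop_config <- function(..., class = "gfba_config_error") {
  stop(errorCondition(paste0(...), class = class))
}

stop_data <- function(...) stop_config(..., class = "gfba_data_error")

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_config(sprintf("'%s' must be a single finite number in [%s, %s]",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}

check_interval <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2] ||
      x[1] < lower || x[2] > upper) {
    stop_config(sprintf("'%s' must be a numeric interval [lo, hi] within [%s, %s]",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}

# Gaussian white + 1/f ("pink") noise, one column per series.  The 1/f part is
# synthesized in the frequency domain with an analytic normalization so the
# output is deterministic given the RNG state (no empirical rescaling).
colored_noise <- function(n_samples, n_series = 1L, sd = 1, exponent = 1) {
  if (sd <= 0 || n_samples == 0L || n_series == 0L) {
    return(matrix(0, n_samples, n_series))
  }
  if (n_samples < 4L) {
    return(matrix(stats::rnorm(n_samples * n_series, sd = sd),
                  n_samples, n_series))
  }
  m <- stats::nextn(n_samples, c(2L, 3L, 5L))  # smooth FFT length
  w <- matrix(stats::rnorm(m * n_series), m, n_series)
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k)
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)  # DC removed
  norm <- sqrt(sum(scale^2) / m)
  x <- Re(stats::mvfft(stats::mvfft(w) * scale, inverse = TRUE)) / m
  x[seq_len(n_samples), , drop = FALSE] * (sd / norm)
}

white_noise <- function(n_samples, n_series = 1L, sd = 1) {
  if (sd <= 0 || n_samples == 0L || n_series == 0L) {
    return(matrix(0, n_samples, n_series))
  }
  matrix(stats::rnorm(n_samples * n_series, sd = sd), n_samples, n_series)
}

# Sample-grid conventions.  Epoch windows are left-closed right-open on the
# sample grid: a sample at t (ms, relative to onset) belongs to [lo, hi) iff
# lo <= t < hi.  The onset sample is the nearest sample at or after the
# stimulus onset time.
epoch_sample_offsets <- function(window_ms, fs) {
  lo <- ceiling(window_ms[1] * fs / 1000 - 1e-9)
  hi <- ceiling(window_ms[2] * fs / 1000 - 1e-9) - 1
  if (hi < lo) stop_config("epoch window contains no samples")
  seq.int(lo, hi)
}

time_window_idx <- function(time_ms, window_ms) {
  which(time_ms >= window_ms[1] - 1e-9 & time_ms < window_ms[2] - 1e-9)
}

onset_sample <- function(onset_s, fs) {
  as.integer(ceiling(onset_s * fs - 1e-9))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
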