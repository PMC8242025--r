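# Condition averaging, difference waves, channel pooling, grand averages,
# mean amplitudes and the display-only Gaussian smoother.

new_waveform <- function(data, time_ms, channels, sampling_rate, n_trials,
                         label = list()) {
  data <- matrix(data, nrow = length(channels),
                 dimnames = list(channels, NULL))
  stopifnot(ncol(data) == length(time_ms))
  structure(list(data = data, time_ms = time_ms, channels = channels,
                 sampling_rate = sampling_rate, n_trials = n_trials,
                 label = label),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  lbl <- paste(unlist(x$label), collapse = " ")
  cat("<waveform> ", lbl, if (nzchar(lbl)) ": " else "",
      length(x$channels), " channel(s) x ", ncol(x$data), " samples, n = ",
      paste(x$n_trials, collapse = "/"), " trials\n", sep = "")
  invisible(x)
}

same_axes <- function(a, b) {
  isTRUE(all.equal(a$time_ms, b$time_ms)) && identical(a$channels, b$channels)
}

#' Average epochs of one task x trial-type condition
#'
#' Arithmetic mean over the selected epochs.  Only ERP-eligible trials
#' (after [filter_behavior()]) that survived artifact rejection enter the
#' average; never-target (magenta) probes never enter the PC/DC/nontarget
#' averages.
#'
#' @param epochs a baseline-corrected `epoch_set` (post rejection).
#' @param trials flagged trial table of the same subject.
#' @param task,trial_type the condition cell to average.
#' @return A `waveform` with the contributing trial count.
#' @export
average_condition <- function(epochs, trials, task, trial_type) {
  if (is.null(trials$erp_eligible)) {
    stop_config("trials carry no eligibility flags; run filter_behavior() first")
  }
  if (!trial_type %in% c("PC", "DC", "nontarget")) {
    stop_config("trial_type must be one of PC, DC, nontarget")
  }
  uids <- trials$uid[trials$erp_eligible & trials$task == task &
                       trials$trial_type == trial_type]
  sel <- which(epochs$trial_ids %in% uids)
  if (length(sel) == 0L) {
    stop_config("no usable trials in cell task=", task,
                ", trial_type=", trial_type)
  }
  avg <- apply(epochs$data[sel, , , drop = FALSE], c(2L, 3L), mean)
  new_waveform(avg, epochs$time_ms, epochs$channels, epochs$sampling_rate,
               n_trials = length(sel),
               label = list(task = task, trial_type = trial_type))
}

#' Average the epochs with the given trial ids
#'
#' Lower-level companion of [average_condition()] for conditional averages
#' (RT-split or repetition-split bins).
#'
#' @param epochs an `epoch_set`.
#' @param uids trial ids to average.
#' @param label descriptive label list attached to the waveform.
#' @return A `waveform`.
#' @export
average_trials <- function(epochs, uids, label = list()) {
  sel <- which(epochs$trial_ids %in% uids)
  if (length(sel) == 0L) stop_config("no matching epochs to average")
  avg <- apply(epochs$data[sel, , , drop = FALSE], c(2L, 3L), mean)
  new_waveform(avg, epochs$time_ms, epochs$channels, epochs$sampling_rate,
               n_trials = length(sel), label = label)
}

#' Sample-wise difference of two waveforms
#'
#' The standard contrasts are DC minus nontarget and PC minus nontarget.
#'
#' @param a,b `waveform`s on identical time axes and channels.
#' @return A `waveform`; `n_trials` records both operand counts.
#' @export
difference_wave <- function(a, b) {
  if (!same_axes(a, b)) stop_config("waveforms have mismatching axes or channels")
  lab_of <- function(w) paste(unlist(w$label[c("task", "trial_type")]),
                              collapse = " ")
  new_waveform(a$data - b$data, a$time_ms, a$channels, a$sampling_rate,
               n_trials = c(a = sum(a$n_trials), b = sum(b$n_trials)),
               label = list(contrast = paste(lab_of(a), "-", lab_of(b)),
                            task = a$label$task))
}

#' Pool channels of a waveform
#'
#' Arithmetic mean across the named channels (default PO3/PO7, the
#' parieto-occipital pair contralateral to the probe).
#'
#' @param w a `waveform`.
#' @param channels channels to pool.
#' @return A single-channel `waveform` named `pooled`.
#' @export
pool_channels <- function(w, channels = c("PO3", "PO7")) {
  i <- match(channels, w$channels)
  if (anyNA(i)) {
    stop_config("channel(s) not present: ",
                paste(channels[is.na(i)], collapse = ", "))
  }
  pooled <- colMeans(w$data[i, , drop = FALSE])
  new_waveform(pooled, w$time_ms, "pooled", w$sampling_rate, w$n_trials,
               label = c(w$label, list(pooled = paste(channels, collapse = "+"))))
}

#' Grand average across subjects
#'
#' Unweighted mean across subject waveforms carrying the same condition
#' label, regardless of per-subject trial counts.
#'
#' @param waves list of subject-level `waveform`s.
#' @return A `waveform` labelled as grand average; `n_trials` is the number
#'   of subjects.
#' @export
grand_average <- function(waves) {
  if (length(waves) == 0L) stop_config("no waveforms to average")
  ref <- waves[[1]]
  key <- function(w) paste(unlist(w$label[c("task", "trial_type", "contrast")]),
                           collapse = "|")
  for (w in waves[-1]) {
    if (!same_axes(ref, w)) stop_config("subject waveforms on different axes")
    if (!identical(key(ref), key(w))) {
      stop_config("cannot grand-average waveforms with mixed labels")
    }
  }
  acc <- Reduce(`+`, lapply(waves, function(w) w$data))
  new_waveform(acc / length(waves), ref$time_ms, ref$channels,
               ref$sampling_rate, n_trials = length(waves),
               label = c(ref$label, list(grand = TRUE)))
}

#' Mean amplitude over a time window
#'
#' Mean over samples with `lo <= t < hi` (left-closed right-open on the
#' sample grid).  Canonical windows are the early (73--96 ms) and late
#' (167--254 ms) ranges.
#'
#' @param w a `waveform`.
#' @param window_ms the window in ms.
#' @return Named numeric vector, one value per channel (a scalar for
#'   single-channel waveforms).
#' @export
mean_amplitude <- function(w, window_ms) {
  idx <- time_window_idx(w$time_ms, window_ms)
  if (length(idx) == 0L) stop_config("window contains no samples")
  out <- rowMeans(w$data[, idx, drop = FALSE])
  if (length(out) == 1L) unname(out) else out
}

#' Gaussian low-pass smoother (display only)
#'
#' Convolution with a Gaussian kernel whose amplitude response equals 0.5 at
#' the half-amplitude cutoff: `sigma_t = sqrt(ln 2 / (2 pi^2 fc^2))`
#' (about 8.15 ms at 23 Hz).  Edges are handled by reflection padding.
#' Intended for plots only -- statistics run on unfiltered data -- so the
#' output is flagged `display_only`.
#'
#' @param w a `waveform`.
#' @param half_amp_cutoff_hz half-amplitude cutoff frequency in Hz.
#' @return The smoothed `waveform`.
#' @export
gaussian_lowpass <- function(w, half_amp_cutoff_hz = 23) {
  check_number(half_amp_cutoff_hz, "half_amp_cutoff_hz", lower = 1e-9)
  sigma_s <- sqrt(log(2) / (2 * pi^2 * half_amp_cutoff_hz^2)) * w$sampling_rate
  r <- max(1L, as.integer(ceiling(4 * sigma_s)))
  kernel <- exp(-(seq.int(-r, r))^2 / (2 * sigma_s^2))
  kernel <- kernel / sum(kernel)
  n <- ncol(w$data)
  if (n < r + 2L) stop_config("waveform too short for the smoothing kernel")
  smooth_row <- function(x) {
    padded <- c(x[(r + 1L):2L], x, x[(n - 1L):(n - r)])
    as.numeric(stats::filter(padded, kernel, sides = 2L))[(r + 1L):(r + n)]
  }
  w$data <- t(apply(w$data, 1L, smooth_row))
  w$label$display_only <- TRUE
  w
}
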