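# Behavioral filtering, re-referencing, epoching, artifact rejection and
# baseline correction.

new_epoch_set <- function(data, time_ms, channels, sampling_rate, trial_ids,
                          baseline_applied = FALSE) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(time_ms),
            dim(data)[1] == length(trial_ids))
  if (anyDuplicated(trial_ids)) stop_config("trial ids must be unique")
  structure(list(data = data, time_ms = time_ms, channels = channels,
                 sampling_rate = sampling_rate, trial_ids = trial_ids,
                 baseline_applied = baseline_applied),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples [",
      round(min(x$time_ms), 1), ", ", round(max(x$time_ms), 1),
      "] ms, baseline ", if (x$baseline_applied) "applied" else "not applied",
      "\n", sep = "")
  invisible(x)
}

#' Flag behaviorally invalid trials
#'
#' Adds exclusion flags: `anticipatory` (RT < 200 ms), `delayed`
#' (RT > 1300 ms; both strict inequalities), `incorrect`, and `invalid_rt`
#' (missing RT on a responded trial).  A trial is `erp_eligible` when none
#' of these is set.  Reaction-time summaries downstream use correct,
#' in-range trials only.
#'
#' @param trials trial table with `rt_ms` and `correct`.
#' @param anticipatory_ms,delayed_ms the exclusion thresholds in ms.
#' @return `trials` with the flag columns appended.
#' @export
filter_behavior <- function(trials, anticipatory_ms = 200, delayed_ms = 1300) {
  rt <- trials$rt_ms
  trials$invalid_rt <- is.na(rt)
  trials$anticipatory <- !is.na(rt) & rt < anticipatory_ms
  trials$delayed <- !is.na(rt) & rt > delayed_ms
  trials$incorrect <- is.na(trials$correct) | !trials$correct
  trials$erp_eligible <- !trials$invalid_rt & !trials$anticipatory &
    !trials$delayed & !trials$incorrect
  trials
}

#' Summarize accuracy and reaction time per task and trial type
#'
#' Produces the 2 (task) x 3 (PC/DC/nontarget) behavioural table: accuracy
#' as percent correct among valid (in-range, responded) trials and mean RT
#' over correct in-range trials.  Never-target (magenta) probes are
#' excluded.  Empty cells are reported as `NA`, not zero.
#'
#' @param trials trial table after [filter_behavior()].
#' @return `data.frame` with columns task, trial_type, n_valid, n_rt,
#'   accuracy_pct, mean_rt_ms.
#' @export
summarize_behavior <- function(trials) {
  if (is.null(trials$erp_eligible)) {
    stop_config("run filter_behavior() before summarize_behavior()")
  }
  dt <- data.table::as.data.table(trials)
  dt <- dt[trial_type %in% c("PC", "DC", "nontarget")]
  dt[, valid := !invalid_rt & !anticipatory & !delayed]
  agg <- dt[, {
    acc <- if (any(valid)) 100 * mean(correct[valid]) else NA_real_
    use <- valid & correct
    list(n_valid = sum(valid), n_rt = sum(use),
         accuracy_pct = acc,
         mean_rt_ms = if (any(use)) mean(rt_ms[use]) else NA_real_)
  }, by = list(task, trial_type)]
  frame <- data.table::CJ(task = sort(unique(trials$task)),
                          trial_type = c("PC", "DC", "nontarget"))
  out <- agg[frame, on = c("task", "trial_type")]
  out[is.na(n_valid), `:=`(n_valid = 0L, n_rt = 0L)]
  as.data.frame(out)
}

#' Re-reference a recording to the mastoid mean
#'
#' Under a right-mastoid online reference, subtracting `weight` (default
#' one half) of the recorded left-mastoid channel from every channel yields
#' the linked-mastoid equivalent: the implied reference becomes the mastoid
#' average.  Mastoid channels are retained.
#'
#' @param recording a `continuous_recording`.
#' @param weight weight of the recorded left mastoid (default 0.5).
#' @param mastoid_left name of the left mastoid channel.
#' @return The re-referenced recording.
#' @export
rereference <- function(recording, weight = 0.5, mastoid_left = "M1") {
  i <- match(mastoid_left, recording$channels)
  if (is.na(i)) stop_config("mastoid channel '", mastoid_left, "' not found")
  ref <- recording$data[i, ]
  recording$data <- sweep(recording$data, 2L, weight * ref, "-")
  recording
}

#' Extract stimulus-locked epochs from a continuous recording
#'
#' Cuts one epoch per event over the window `[lo, hi)` ms relative to
#' stimulus onset (left-closed right-open on the sample grid, so every epoch
#' has an identical number of samples; the onset sample has time 0).
#' Events too close to a recording edge are dropped with a warning.
#'
#' @param recording a `continuous_recording` with an `events` table.
#' @param trials trial table whose `uid`s match the recording events.
#' @param window_ms epoch window in ms (default `c(-200, 700)`).
#' @return An `epoch_set`.
#' @export
extract_epochs <- function(recording, trials, window_ms = c(-200, 700)) {
  fs <- recording$sampling_rate
  offs <- epoch_sample_offsets(window_ms, fs)
  ev <- recording$events[recording$events$uid %in% trials$uid, , drop = FALSE]
  n_total <- ncol(recording$data)
  ok <- ev$sample + offs[1] >= 0L & ev$sample + offs[length(offs)] <= n_total - 1L
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) too close to a recording edge were dropped")
    ev <- ev[ok, , drop = FALSE]
  }
  if (nrow(ev) == 0L) stop_config("no epochs could be extracted")
  nch <- length(recording$channels)
  idx <- outer(ev$sample, offs, "+") + 1L      # trials x samples
  data <- array(0, dim = c(nrow(ev), nch, length(offs)))
  for (ch in seq_len(nch)) {
    data[, ch, ] <- recording$data[ch, idx]
  }
  new_epoch_set(data, offs * 1000 / fs, recording$channels, fs,
                trial_ids = ev$uid)
}

#' Peak-to-peak artifact rejection
#'
#' An epoch is rejected when its peak-to-peak amplitude (max minus min over
#' the full epoch) exceeds the threshold on any scanned channel.  All
#' non-mastoid channels are scanned by default.  Epoch order is preserved.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (> 0); typical
#'   per-subject values range from 70 to 115 with 100 as default.
#' @param exclude_channels channels not scanned (default: the mastoids).
#' @return A list with `epochs` (kept trials) and `report`, a
#'   `rejection_report` holding the per-epoch per-channel peak-to-peak
#'   table, the rejected flags, the threshold and the rejection fraction.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100,
                             exclude_channels = c("M1", "M2")) {
  if (!is.numeric(threshold_uv) || threshold_uv <= 0) {
    stop_config("'threshold_uv' must be > 0")
  }
  scan <- setdiff(epochs$channels, exclude_channels)
  if (length(scan) == 0L) stop_config("no channels left to scan")
  ci <- match(scan, epochs$channels)
  n_tr <- dim(epochs$data)[1]
  p2p <- matrix(0, n_tr, length(ci), dimnames = list(NULL, scan))
  for (k in seq_along(ci)) {
    m <- epochs$data[, ci[k], , drop = FALSE]
    dim(m) <- dim(m)[c(1, 3)]
    p2p[, k] <- apply(m, 1L, function(v) max(v) - min(v))
  }
  rejected <- rowSums(p2p > threshold_uv) > 0L
  keep <- which(!rejected)
  kept <- new_epoch_set(epochs$data[keep, , , drop = FALSE], epochs$time_ms,
                        epochs$channels, epochs$sampling_rate,
                        epochs$trial_ids[keep], epochs$baseline_applied)
  report <- structure(list(table = data.frame(uid = epochs$trial_ids, p2p,
                                              rejected = rejected,
                                              check.names = FALSE),
                           threshold_uv = threshold_uv,
                           fraction = if (n_tr) mean(rejected) else 0),
                      class = "rejection_report")
  list(epochs = kept, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("<rejection_report> threshold ", x$threshold_uv, " uV, ",
      sum(x$table$rejected), "/", nrow(x$table), " epochs rejected (",
      round(100 * x$fraction, 1), "%)\n", sep = "")
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default: the 150 ms before stimulus onset, `[-150, 0)` ms).
#'
#' @param epochs an `epoch_set`.
#' @param baseline_ms baseline window in ms.
#' @return The corrected `epoch_set` with `baseline_applied = TRUE`.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-150, 0)) {
  idx <- time_window_idx(epochs$time_ms, baseline_ms)
  if (length(idx) == 0L) stop_config("baseline window outside epoch support")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  # element [t, c, s] minus bl[t, c]: recycling over the sample dimension
  epochs$data <- epochs$data - as.vector(bl)
  epochs$baseline_applied <- TRUE
  epochs
}
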