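# Simple base-graphics line plots of condition / difference waveforms with
# marked significance windows.

#' Plot waveforms with marked significance intervals
#'
#' Line plot of one or more (typically pooled, grand-average) waveforms on
#' a shared time axis, with detected significance intervals shaded.
#' Negative is plotted upward, following ERP convention.
#'
#' @param waves named list of `waveform`s (single channel each).
#' @param intervals optional `data.frame` with `onset_ms` / `offset_ms`
#'   columns (e.g. from a `sliding_result`), shaded grey.
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_waveforms <- function(waves, intervals = NULL, file = NULL,
                           main = "ERP waveforms") {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 540)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  time_ms <- waves[[1]]$time_ms
  ys <- lapply(waves, function(w) w$data[1L, ])
  ylim <- rev(range(unlist(ys)))        # negative up
  graphics::plot(NA, xlim = range(time_ms), ylim = ylim,
                 xlab = "time (ms)", ylab = "amplitude (uV)", main = main)
  if (!is.null(intervals) && nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      graphics::rect(intervals$onset_ms[i], ylim[1],
                     intervals$offset_ms[i], ylim[2],
                     col = grDevices::grey(0.9), border = NA)
    }
  }
  graphics::abline(h = 0, v = 0, col = "grey50")
  cols <- seq_along(waves)
  for (i in cols) graphics::lines(time_ms, ys[[i]], col = i, lwd = 2)
  graphics::legend("topright", legend = names(waves), col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}

# Grand difference waves (DC/PC minus nontarget, color task) from pipeline
# artifacts, with the detected COLOR intervals shaded.
plot_pipeline_waves <- function(dir, file) {
  waveforms <- as.data.frame(read_body(file.path(dir, "waveforms.tsv")))
  wf <- waveforms[waveforms$set == "cell" & waveforms$task == "color", ]
  time_ms <- sort(unique(wf$time_ms))
  gmean <- function(type) {
    sel <- wf[wf$trial_type == type, ]
    as.numeric(tapply(sel$amp, sel$time_ms, mean)[as.character(time_ms)])
  }
  fs <- 1000 / stats::median(diff(time_ms))
  mk <- function(type) {
    new_waveform(gmean(type) - gmean("nontarget"), time_ms, "pooled", fs,
                 n_trials = length(unique(wf$subject)),
                 label = list(contrast = paste(type, "- nontarget")))
  }
  stats_json <- jsonlite::read_json(file.path(dir, "stats.json"),
                                    simplifyVector = TRUE)
  iv <- stats_json$intervals[["TASK:COLOR"]]
  plot_waveforms(list(`DC - nontarget` = gaussian_lowpass(mk("DC")),
                      `PC - nontarget` = gaussian_lowpass(mk("PC"))),
                 intervals = if (is.data.frame(iv)) iv,
                 file = file, main = "Color task difference waves (display-filtered)")
}
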