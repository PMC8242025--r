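# Reaction-time median/quartile splits per stimulus display and the
# target-repetition split.

# A display is one unique stimulus: subject x task x color pair x target
# color x target orientation x probe color (20 distinct displays per task
# and color pair).
display_key_cols <- c("subject", "task", "color_pair", "target_color",
                      "target_orientation", "probe_color")

split_eligible <- function(trials) {
  if (is.null(trials$erp_eligible)) {
    stop_config("run filter_behavior() before splitting")
  }
  trials[trials$erp_eligible, , drop = FALSE]
}

empty_assignment <- function(split) {
  data.frame(subject = integer(0), uid = integer(0),
             split = character(0), tag = character(0),
             stringsAsFactors = FALSE)
}

#' Median reaction-time split per stimulus display
#'
#' Within every display group, trials with RT strictly below the group
#' median are tagged `fast`, strictly above `slow`; trials exactly at the
#' median are excluded by default (only "slower" and "faster" trials are
#' tagged) or assigned to `slow` with `tie = "slow"`.  Groups of fewer than
#' two trials are excluded.  Only correct, in-range trials are considered.
#' Tags are pooled across displays within trial type downstream.
#'
#' @param trials flagged trial table (after [filter_behavior()]).
#' @param tie `"exclude"` (default) or `"slow"`.
#' @return `data.frame` (subject, uid, split, tag) with tag in
#'   fast/slow/excluded.
#' @export
median_rt_split <- function(trials, tie = c("exclude", "slow")) {
  tie <- match.arg(tie)
  el <- split_eligible(trials)
  if (nrow(el) == 0L) return(empty_assignment("median_rt"))
  dt <- data.table::as.data.table(el[, c(display_key_cols, "uid", "rt_ms")])
  dt[, `:=`(med = stats::median(rt_ms), n_grp = .N), by = display_key_cols]
  dt[, tag := data.table::fifelse(
    n_grp < 2L, "excluded",
    data.table::fifelse(rt_ms < med, "fast",
                        data.table::fifelse(rt_ms > med, "slow",
                                            if (tie == "slow") "slow" else "excluded")))]
  data.frame(subject = dt$subject, uid = dt$uid, split = "median_rt",
             tag = dt$tag, stringsAsFactors = FALSE)
}

#' Quartile reaction-time split per stimulus display
#'
#' Rank-based quartile bins within each display group: trial ranks (ties
#' broken by occurrence order, deterministic) are cut at n/4 boundaries,
#' quartile 1 being the fastest and 4 the slowest.  Groups of fewer than
#' four trials are excluded.
#'
#' @inheritParams median_rt_split
#' @return `data.frame` (subject, uid, split, tag) with tag in Q1..Q4 or
#'   excluded.
#' @export
quartile_rt_split <- function(trials) {
  el <- split_eligible(trials)
  if (nrow(el) == 0L) return(empty_assignment("quartile_rt"))
  dt <- data.table::as.data.table(el[, c(display_key_cols, "uid", "rt_ms")])
  dt[, n_grp := .N, by = display_key_cols]
  dt[, r := rank(rt_ms, ties.method = "first"), by = display_key_cols]
  dt[, tag := data.table::fifelse(n_grp < 4L, "excluded",
                                  paste0("Q", ceiling(4 * r / n_grp)))]
  data.frame(subject = dt$subject, uid = dt$uid, split = "quartile_rt",
             tag = dt$tag, stringsAsFactors = FALSE)
}

#' Target-repetition split
#'
#' Tags every trial `repeat` when the target color equals that of the
#' immediately preceding trial of the same block, `switch` otherwise;
#' each block's first trial is `undefined` (excluded from both bins).
#' Because the target color is drawn independently per trial, the two bins
#' are equally sized in expectation.
#'
#' @param trials trial table ordered within blocks (error if not).
#' @return `data.frame` (subject, uid, split, tag).
#' @export
repetition_split <- function(trials) {
  if (nrow(trials) == 0L) return(empty_assignment("repetition"))
  dt <- data.table::as.data.table(
    trials[, c("subject", "block", "trial", "uid", "target_color")])
  unordered <- dt[, list(bad = is.unsorted(trial, strictly = TRUE)),
                  by = list(subject, block)]
  if (any(unordered$bad)) {
    stop_config("trials must be ordered within blocks")
  }
  dt[, prev := data.table::shift(target_color), by = list(subject, block)]
  dt[, tag := data.table::fifelse(is.na(prev), "undefined",
                                  data.table::fifelse(target_color == prev,
                                                      "repeat", "switch"))]
  data.frame(subject = dt$subject, uid = dt$uid, split = "repetition",
             tag = dt$tag, stringsAsFactors = FALSE)
}
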