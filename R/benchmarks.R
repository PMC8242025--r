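# Simulation benchmarks: parameter recovery, null control and split
# recovery under the generator's study conditions.  Used by the validation
# suite and the acceptance script.

#' Detection-rate benchmark for the sliding 2 x 3 rANOVA
#'
#' Simulates `n_datasets` cohorts of condition averages under the given
#' design and effects (via [simulate_condition_averages()]) and scores, per
#' dataset, whether the sliding scan detects a TASK x COLOR interval
#' overlapping the injected early DC window and a COLOR interval
#' overlapping the injected late window.
#'
#' @param n_datasets number of simulated cohorts.
#' @param config a [paradigm_config()].
#' @param effects an [effect_params()].
#' @param seed master seed.
#' @return List with `early_rate`, `late_rate` (fractions of datasets),
#'   `n_datasets` and the per-dataset hit vectors.
#' @export
benchmark_detection <- function(n_datasets = 50L, config = paradigm_config(),
                                effects = effect_params(), seed = 1L) {
  early_hit <- late_hit <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    sim <- simulate_condition_averages(config, effects,
                                       seed = derive_seed(seed, 11L, d))
    scan <- suppressMessages(sliding_anova(sim$cells, sim$time_ms))
    ie <- scan$intervals[["TASK:COLOR"]]
    il <- scan$intervals[["COLOR"]]
    early_hit[d] <- any(ie$onset_ms <= effects$early_dc_window[2] &
                          ie$offset_ms >= effects$early_dc_window[1])
    late_hit[d] <- any(il$onset_ms <= effects$late_pc_window[2] &
                         il$offset_ms >= effects$late_pc_window[1])
  }
  list(early_rate = mean(early_hit), late_rate = mean(late_hit),
       n_datasets = n_datasets, early_hit = early_hit, late_hit = late_hit)
}

#' Null-control benchmark for the sliding scan
#'
#' Simulates cohorts with every injected effect amplitude set to zero and
#' measures the per-window false-positive rate of the sliding rANOVA at the
#' corrected alpha, along with the fraction of datasets producing at least
#' one detected interval under the consecutive-samples rule.
#'
#' @inheritParams benchmark_detection
#' @return List with `fpr`, `alpha`, `n_tests`, `any_interval_fraction` and
#'   `n_datasets`.
#' @export
benchmark_null_fpr <- function(n_datasets = 200L, config = paradigm_config(),
                               effects = effect_params(), seed = 1L) {
  null_eff <- effects
  null_eff$early_dc_amp <- 0
  null_eff$late_pc_amp <- 0
  null_eff$late_dc_amp <- 0
  null_eff$early_amp_jitter_sd <- 0
  n_sig <- n_tests <- 0L
  any_int <- logical(n_datasets)
  alpha <- NA_real_
  for (d in seq_len(n_datasets)) {
    sim <- simulate_condition_averages(config, null_eff,
                                       seed = derive_seed(seed, 21L, d))
    scan <- suppressMessages(sliding_anova(sim$cells, sim$time_ms))
    alpha <- scan$alpha
    n_sig <- n_sig + sum(scan$p < alpha)
    n_tests <- n_tests + length(scan$p)
    any_int[d] <- any(vapply(scan$intervals, nrow, 1L) > 0L)
  }
  list(fpr = n_sig / n_tests, alpha = alpha, n_tests = n_tests,
       any_interval_fraction = mean(any_int), n_datasets = n_datasets)
}

#' Oracle-agreement benchmark for the within-subject ANOVA
#'
#' Compares [rm_anova()] F statistics with those of an independent
#' general-linear-model implementation (`stats::aov` with
#' `Error(subject/(A*B))` strata) on random small balanced designs with
#' correlated, heteroscedastic cell scores.
#'
#' @param n_designs number of random designs.
#' @param seed master seed.
#' @return List with `max_abs_dF`, the largest |F difference| over all
#'   designs and effects, and `n_designs`.
#' @export
benchmark_anova_oracle <- function(n_designs = 50L, seed = 1L) {
  with_seed(seed, {
    worst <- 0
    for (k in seq_len(n_designs)) {
      a <- sample(2:4, 1L)
      b <- sample(2:3, 1L)
      n <- sample(4:9, 1L)
      y <- matrix(stats::rnorm(n * a * b, sd = rep(stats::runif(a * b, 0.5, 2),
                                                   each = n)), n, a * b)
      y <- y + stats::rnorm(n)                     # subject effect
      ours <- rm_anova(y, a, b)
      dat <- data.frame(y = as.vector(t(y)),
                        s = factor(rep(seq_len(n), each = a * b)),
                        A = factor(rep(rep(seq_len(a), each = b), n)),
                        B = factor(rep(rep(seq_len(b), a), n)))
      fit <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = dat))
      f_or <- c(fit[["Error: s:A"]][[1]]["A", "F value"],
                fit[["Error: s:B"]][[1]]["B", "F value"],
                fit[["Error: s:A:B"]][[1]]["A:B", "F value"])
      worst <- max(worst, abs(ours$F - f_or))
    }
    list(max_abs_dF = worst, n_designs = n_designs)
  })
}

# Trial-level chain for one subject's color task: synthesize epochs, reject
# artifacts, baseline-correct, median-split and return early/late DC minus
# nontarget amplitudes for the fast and slow bins.
subject_split_amplitudes <- function(config, effects, subject, seed,
                                     early_window_ms, late_window_ms,
                                     preproc = pipeline_defaults()$preprocessing,
                                     tie = "exclude") {
  trials <- design_subject_seeded(config, subject, derive_seed(seed, 1L))
  trials <- simulate_behavior(trials, effects, seed = derive_seed(seed, 2L))
  trials <- filter_behavior(trials)
  trc <- trials[trials$task == "color", , drop = FALSE]
  ep <- synthesize_epochs(trc, effects, config, seed = derive_seed(seed, 3L))
  rej <- reject_artifacts(ep, preproc$reject_threshold_uv,
                          exclude_channels = unname(config$mastoid_channels))
  ep <- baseline_correct(rej$epochs, preproc$baseline_ms)
  med <- median_rt_split(trc, tie = tie)
  amp <- function(type, tag, window) {
    uids <- intersect(trc$uid[trc$erp_eligible & trc$trial_type == type],
                      med$uid[med$tag == tag])
    if (!any(ep$trial_ids %in% uids)) return(NA_real_)
    mean_amplitude(pool_channels(average_trials(ep, uids),
                                 config$analysis_channels), window)
  }
  c(early_fast = amp("DC", "fast", early_window_ms) -
      amp("nontarget", "fast", early_window_ms),
    early_slow = amp("DC", "slow", early_window_ms) -
      amp("nontarget", "slow", early_window_ms),
    late_fast = amp("DC", "fast", late_window_ms) -
      amp("nontarget", "fast", late_window_ms),
    late_slow = amp("DC", "slow", late_window_ms) -
      amp("nontarget", "slow", late_window_ms))
}

design_subject_seeded <- function(config, subject, seed) {
  with_seed(seed, design_subject(config, subject))
}

#' Median RT-split recovery benchmark
#'
#' For each simulated cohort, runs the full trial-level chain (design,
#' behaviour, epoch synthesis, artifact rejection, baseline correction,
#' per-display median RT split, conditional averaging) and scores whether
#' the cohort-mean early-window DC minus nontarget amplitude is more
#' negative for fast than for slow trials -- the sign of the fast/slow
#' early-modulation pattern the generator's EEG--RT coupling produces.
#'
#' @inheritParams benchmark_detection
#' @param n_subjects subjects per cohort.
#' @param early_window_ms,late_window_ms amplitude windows.
#' @return List with `sign_rate`, mean fast and slow early amplitudes and
#'   the per-dataset values.
#' @export
benchmark_rt_split <- function(n_datasets = 50L, config = paradigm_config(),
                               effects = effect_params(), seed = 1L,
                               n_subjects = config$n_subjects,
                               early_window_ms = effects$early_dc_window,
                               late_window_ms = effects$late_pc_window) {
  fast <- slow <- numeric(n_datasets)
  for (d in seq_len(n_datasets)) {
    vals <- vapply(seq_len(n_subjects), function(s) {
      subject_split_amplitudes(config, effects, s,
                               seed = derive_seed(seed, 31L, d, s),
                               early_window_ms, late_window_ms)
    }, numeric(4L))
    fast[d] <- mean(vals["early_fast", ], na.rm = TRUE)
    slow[d] <- mean(vals["early_slow", ], na.rm = TRUE)
  }
  list(sign_rate = mean(fast < slow), fast_mean = mean(fast),
       slow_mean = mean(slow), fast = fast, slow = slow,
       n_datasets = n_datasets)
}

#' Target-repetition benefit recovery
#'
#' Simulates one cohort's behaviour and estimates the repeat-vs-switch
#' reaction-time difference (correct, in-range trials) with its paired
#' standard error across subjects.
#'
#' @inheritParams benchmark_detection
#' @return List with `benefit_ms`, `se_ms`, `t`, `p` and `n_subjects`.
#' @export
benchmark_repetition <- function(config = paradigm_config(),
                                 effects = effect_params(), seed = 1L) {
  trials <- simulate_dataset(config, effects, seed = seed)
  trials <- filter_behavior(trials)
  el <- trials[trials$erp_eligible & trials$repetition != "undefined", ]
  subjects <- sort(unique(el$subject))
  diffs <- vapply(subjects, function(s) {
    es <- el[el$subject == s, ]
    mean(es$rt_ms[es$repetition == "switch"]) -
      mean(es$rt_ms[es$repetition == "repeat"])
  }, numeric(1L))
  tt <- paired_t(diffs, rep(0, length(diffs)))
  list(benefit_ms = mean(diffs),
       se_ms = stats::sd(diffs) / sqrt(length(diffs)),
       t = tt$t, p = tt$p, n_subjects = length(subjects))
}
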