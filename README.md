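# gfbascan

Simulation and sliding-window analysis of global feature-based attention
(GFBA) ERP experiments in the unattended probe paradigm.

## The problem

When observers must identify which of two possible target colors is
present on a given trial, the brain has to bias color selectivity "on the
fly": enhance the present target color (PC) and handle the distracting
alternative target color (DC). The unattended probe paradigm measures
this bias remotely: a task-irrelevant color probe in the opposite
hemifield evokes an ERP whose amplitude tracks how strongly its color is
attended, because feature-based attention spreads across the visual
field. The GFBA effect is the difference wave between attended-color and
never-relevant (non-target) probes at parieto-occipital channels
(PO3/PO7, pooled), and the interesting dynamics are an early (~73–96 ms)
DC-only negativity during color discrimination, later (~167–254 ms)
negativities for both attended colors, and trial-level couplings: a DC
response-time cost, an ~40 ms target-repetition benefit, and faster
responses on trials with a larger early DC modulation.

`gfbascan` provides this entire analysis as a tested, reusable R
pipeline, together with a synthetic-data generator that reproduces the
design (2 tasks × 2 blockwise color pairs × 5 probe colors, 6 × 180
trials per task, EEG at 254.31 Hz) so that every stage can be exercised
and validated without any recordings. It is aimed at EEG/MEG
methodologists who want a transparent reference implementation of the
statistical machinery, and at simulation studies of that machinery.

## What it implements

* **Generator** — trial tables under the blockwise pseudorandomization
  constraints; reaction times/accuracy with DC cost, repetition benefit
  and EEG–RT coupling; continuous multichannel EEG (or epochs directly)
  with injected boxcar condition effects, white + 1/f noise and blink
  transients.
* **Preprocessing** — behavioural filters (RT < 200 ms, > 1300 ms,
  errors), linked-mastoid re-referencing, epoching over [−200, 700) ms,
  peak-to-peak artifact rejection, 150 ms-prestimulus baseline.
* **ERP** — condition averages, DC/PC − non-target difference waves,
  PO3/PO7 pooling, grand averages, window mean amplitudes, and a
  display-only 23 Hz half-amplitude Gaussian smoother.
* **Statistics** — a from-scratch two-way within-subject ANOVA with
  Greenhouse–Geisser correction (`rm_anova`), paired t-tests, the
  corrected alpha `1 − (1 − α)^(2·fc/fs)` (≈ 0.02 at fc = 50 Hz,
  fs = 254.31 Hz), sample-by-sample sliding scans with 3-sample
  (11.8 ms) windows, and the ≥ 5-consecutive-samples onset rule.
* **Splits** — per-stimulus-display median and quartile RT splits and the
  target-repetition split, feeding conditional ERP averages and the
  EARLYLATE × FASTSLOW interaction test.
* **Source stage** — toy minimum-norm least-squares inverse
  `W = Lᵀ(LLᵀ + λI)⁻¹`, ring-geometry leadfields, ROI source waveforms,
  and leadfield-based sensor repositioning.

## Worked example

```r
library(gfbascan)

config <- pipeline_config(seed = 7)   # 22 subjects, 6 x 180 trials/task
report <- run_pipeline(config, "gfba-demo")

round(report$stats$alpha, 4)
#> 0.02
report$behavior
#>          task trial_type n_valid n_rt accuracy_pct mean_rt_ms
#> 1       color         DC    4732 4459        94.23      407.5
#> 2       color         PC    4756 4522        95.08      380.0
#> 3       color  nontarget    9536 9083        95.25      380.2
#> 4 orientation         DC    4664 4441        95.22      381.4
#> 5 orientation         PC    4752 4500        94.70      379.6
#> 6 orientation  nontarget    9487 9002        94.89      380.1
```

The behavioural table shows the simulated performance profile: all cells
fast (< 410 ms) and accurate (> 92 %), with the slowest responses where
the probe carries the distracting alternative target color during color
discrimination. The sliding 2 × 3 rANOVA then recovers the injected
effect windows at the corrected alpha:

```r
report$stats$intervals
#> TASK:       161.2-247.7 ms
#> COLOR:       66.8- 90.4 ms   165.2-251.7 ms
#> TASK:COLOR:  70.8- 90.4 ms   165.2-243.8 ms
```

The early TASK × COLOR interaction interval (70.8–90.4 ms) and the late
COLOR interval (165.2–251.7 ms) bracket the generator's injected windows
(73–96 and 167–254 ms) to within one sliding-window width. The splits
stage recovers the behavioural and electrophysiological couplings:

```r
report$splits$repetition_benefit_ms
#> 38.5                                  # injected: 40 ms
report$splits$median_interaction
#>               effect df1 df2      F epsilon        p     p_gg
#> 1          EARLYLATE   1  21 12.637       1 0.001873 0.001873
#> 2           FASTSLOW   1  21  5.828       1 0.024980 0.024980
#> 3 EARLYLATE:FASTSLOW   1  21 13.852       1 0.001261 0.001261
```

The significant EARLYLATE × FASTSLOW interaction is the fast/slow
crossover: fast-response trials carry the larger early DC modulation.
Finally the toy source stage localizes the simulated generator exactly
and repositions a displaced sensor ring with sub-percent error:

```r
report$source$localization_error_steps
#> 0
report$source$reposition_rel_error
#> 0.0086
```

All artifacts (trial tables, condition waveforms, p-value series, split
assignments, the JSON report) are written to the output directory as
schema-stamped TSV/JSON text files.

## Command line

```sh
Rscript inst/cli/gfba.R all --config config.yaml --out run1 --seed 7
Rscript inst/cli/gfba.R simulate --config config.yaml --out run2
Rscript inst/cli/gfba.R erp      --config config.yaml --out run2   # etc.
```

Stages compose: running them individually produces the same report as
`all`. Exit codes: 0 success, 2 configuration error, 3 data error,
4 stage failure. `write_config(pipeline_config(), "config.yaml")`
produces a template configuration.

## Package layout

* `R/` — generator, preprocessing, ERP, statistics, splits, source
  estimation, IO, pipeline orchestration, benchmarks.
* `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
* `vignettes/gfba-pipeline.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical conventions, limitations.
* `inst/cli/gfba.R` — command-line front end.
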