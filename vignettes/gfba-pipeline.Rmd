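---
title: "Simulating and analysing global feature-based attention ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing global feature-based attention ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfbascan)
```

## The experiment this package models

`gfbascan` implements, end to end, the analysis of an *unattended probe
paradigm* (UPP) experiment on global feature-based attention (GFBA) to
color. A participant covertly attends a target in one visual hemifield and
discriminates either its color or its orientation, while a task-irrelevant
color probe is flashed in the opposite hemifield. Because feature-based
attention spreads across the visual field, the ERP evoked by the probe
indexes how strongly each color is being selected. On every trial the
target takes one of two blockwise-assigned colors, so the probe can carry
the *present target color* (PC), the *distracting alternative target
color* (DC), a *non-target* color, or a fifth color that is never a target
and is excluded from the main analyses. GFBA effects are measured as
difference waves, PC &minus; non-target and DC &minus; non-target, at the
parieto-occipital channels contralateral to the probe (PO3/PO7, pooled).

The scientific signature the pipeline is built to detect and characterise
is a crossover in time: an early (around 73–96 ms) negativity that appears
only for DC probes during the color task, and later (around 167–254 ms)
negativities for the attended colors with the strongest modulation for the
PC. Trial-level couplings matter too: responses are slower on color-task
DC trials, about 40 ms faster when the target color repeats from the
previous trial, and faster on trials whose early DC negativity is larger
in magnitude.

Every stage runs on synthetic data, so the full chain is testable without
any recordings: generation &rarr; behavioural filtering &rarr;
re-referencing &rarr; epoching &rarr; peak-to-peak artifact rejection
&rarr; baseline correction &rarr; condition averaging and difference waves
&rarr; sliding-window repeated-measures statistics &rarr; RT and
repetition splits &rarr; a toy minimum-norm source stage.

## The synthetic-data generator

`paradigm_config()` fixes the design: 22 subjects, two tasks, 6 blocks of
180 trials per task, target-color pairs red/green and blue/yellow, probe
color uniform over five colors, 300 ms stimuli with 1000–1200 ms uniform
inter-stimulus intervals, and EEG at 254.31 Hz. Blocks are
pseudorandomized under two constraints — the color pair is never repeated
on subsequent blocks and the task changes every second block — with the
four possible orders cycled across subjects. These defaults imply the two
design identities the tests pin down: 6 &times; 180 / 5 = 216 expected
trials per probe type per task, and (3 &times; 180) / 20 = 27 occurrences
of each unique display (target color &times; orientation &times; probe
color) per color set.

`effect_params()` fixes the effect geometry and the noise model.
Choices the underlying study does not dictate were made once, on standard
EEG grounds, and are all configurable:

* **ERP template.** The fixed probe-evoked response is a smooth biphasic
  kernel (Gaussian P1 at 100 ms, +3 µV, sd 20 ms; N1 at 170 ms, &minus;4
  µV, sd 30 ms). Only the condition *deltas* matter for the statistics,
  so the template morphology is cosmetic.
* **Condition deltas.** Boxcar offsets over the early (73–96 ms) and late
  (167–254 ms) windows: &minus;0.8 µV early DC (color task only),
  &minus;1.2 µV late PC (halved in the orientation task), &minus;0.5 µV
  late DC. Boxcars make linearity exact: with noise off, every
  downstream averaging stage must recover the injected value to machine
  precision, which the tests assert.
* **Noise.** Per trial and channel, white Gaussian noise (8 µV sd) plus
  1/f noise (4 µV, exponent 1) synthesized in the frequency domain. No
  alpha oscillations are simulated. Blink transients (150 µV, rate 0.02
  per trial) provide artifacts for the rejection stage.
* **Behaviour.** RT = 400 ms base + 25 ms on color-task DC trials
  &minus; 40 ms on target repetitions + coupling &times; the trial's
  early-amplitude deviate + Gaussian noise (60 ms sd), truncated at 50
  ms; accuracy 0.95. These values keep every task &times; type cell mean
  below 410 ms and above 92 % correct, the calibration the behavioural
  tests check.
* **EEG–RT coupling.** Each color-task DC trial draws an early-amplitude
  deviate (sd 1 µV) that is added to the early boxcar *and*, scaled by
  20 ms/µV, to the RT. This shared deviate is a generator construction —
  a minimal mechanism that reproduces the fast/slow crossover pattern —
  not a claim about cortical physiology. The per-trial variability value
  is not empirically constrained; it stays a parameter.

Two generator surfaces exist beside the continuous-recording synthesizer.
`synthesize_epochs()` produces the same signal model directly on the epoch
grid (independent noise per epoch, no continuity between epochs), for
analyses in which the continuous plumbing is not under study.
`simulate_condition_averages()` goes one step further and samples
per-subject condition *averages* directly: for Gaussian white + 1/f noise
the average of n independent noise epochs is distributed exactly as one
noise epoch scaled by 1/&radic;n, so this path is a distributional
identity, not an approximation. The property suites use it for the
detection and null benchmarks; the RT-split benchmark and the pipeline
use the trial-level paths, so both generator routes stay exercised.

What the generator does *not* emulate: alpha rhythms and other structured
oscillations, non-Gaussian artifact families (muscle, electrode drift),
eye movements, overlapping evoked responses, learning or fatigue trends,
and between-subject amplitude differences beyond measurement noise.
Passing tests therefore certify the pipeline's statistical machinery under
its stated noise model, not robustness to every failure mode of real EEG.

## Preprocessing conventions

* **Windows are left-closed, right-open on the sample grid** everywhere:
  a sample at time t belongs to [lo, hi) iff lo &le; t &lt; hi. The
  epoch window [&minus;200, 700) ms at 254.31 Hz therefore contains
  exactly 229 samples, with the onset sample at t = 0 being the nearest
  sample at or after the stimulus onset time.
* **Re-referencing.** With a right-mastoid online reference, subtracting
  half of the recorded left-mastoid channel re-references all channels to
  the mastoid average. The exact weighting in the originating literature
  is not fully specified, so the weight (default 0.5) is a parameter; a
  test verifies the implied-reference algebra.
* **Behavioural filters** use strict inequalities: anticipatory iff RT
  &lt; 200 ms, delayed iff RT &gt; 1300 ms. Incorrect trials are removed
  from ERP averages but retained for accuracy computation.
* **Artifact rejection** flags an epoch when max &minus; min over the
  whole epoch exceeds the threshold on *any* non-mastoid channel
  (default 100 µV; per-subject practice spans roughly 70–115 µV).
  Rejection is idempotent and monotone in the threshold, both asserted
  as properties.
* **Baseline** is the mean over [&minus;150, 0) ms, subtracted per epoch
  and channel; baseline correction commutes with averaging, which is
  asserted numerically.
* No filtering is applied in preprocessing: the acquisition band-pass
  exists only inside the generator, and statistics run on unfiltered
  data. The 23 Hz Gaussian smoother (`gaussian_lowpass()`) is display
  only; its sigma is the unique Gaussian value with amplitude response
  0.5 at the cutoff, &sigma;&nbsp;=&nbsp;&radic;(ln 2 / (2&pi;²f&#99;²))
  &asymp; 8.15 ms at 23 Hz, with reflection padding at the edges.

## The statistics engine

`rm_anova()` is a from-scratch two-way within-subject ANOVA: each effect
is tested against its own subject-by-effect interaction error term, and
the Greenhouse–Geisser epsilon of each effect is the classical estimator
from the covariance of orthonormalized within-subject contrast scores
(for a 2-level factor epsilon is identically 1). Its F statistics agree
with an independent general-linear-model oracle (`stats::aov` with error
strata) to better than 10⁻⁶ across random designs; this agreement is an
acceptance criterion, and the epsilon estimator is cross-checked against
an eigenvalue formulation. A subtlety worth recording: "corrected p never
below uncorrected p" is a theorem only in the significant regime (F
&gt; 1); for F &lt; 1 shrinking both degrees of freedom can lower the
p-value slightly, and we follow standard practice in not clamping it.

The sliding scan (`sliding_anova()`) tests the 2 (TASK) &times; 3 (COLOR)
design sample by sample over 0–300 ms. Each tested sample's value is the
mean amplitude over a 3-sample window (11.8 ms at 254.31 Hz); the window
is left-aligned on the tested sample by default (the aggregation and
alignment are not dictated by the underlying description, so both are
parameters — `align = "center"` and the window width can be changed).
Significance uses the sampling-theory corrected alpha
1 &minus; (1 &minus; 0.05)^(2·f&#99;/f&#115;) &asymp; 0.02 at f&#99; = 50
Hz and f&#115; = 254.31 Hz, and an effect interval requires five or more
successive sub-alpha samples, with the onset at the first sample of the
run. Greenhouse–Geisser correction is applied inside the scan by default
(`use_gg = FALSE` switches it off, since one could also reserve the
correction for omnibus tests). Explorative `sliding_t()` scans keep the
uncorrected 0.05 level. Three effects (TASK, COLOR, interaction) are each
scanned; no further cross-effect correction is applied.

Degenerate cases are defined, not accidental: zero effect and zero error
give F = 0 and p = 1; a zero-variance paired difference yields p = 0 (or
p = 1 when the mean is also zero) with an explicit degeneracy flag.

## Trial splits

The RT median split is computed *per stimulus display* (subject &times;
task &times; color pair &times; target color &times; orientation &times;
probe color — 20 displays per task and pair), so that color- or
response-specific RT differences cannot masquerade as fast/slow
differences. Trials strictly below the display median are fast, strictly
above are slow; the trial exactly at the median is excluded by default
because only "faster" and "slower" trials are well defined — a reading
choice, so `tie = "slow"` exists for sensitivity checks. Quartile splits
use ranks with occurrence-order tie-breaking (deterministic, integer bin
sizes) rather than interpolated quantiles. The repetition split tags a
trial `repeat` iff the target color equals the previous trial's within
the same block; block-initial trials are undefined. Splits are computed
after behavioural filtering; the ERP stage then intersects the split bins
with the artifact-free epochs (the ordering is a design choice we log in
the run report via the per-stage counts).

## Toy source stage

The minimum-norm least-squares (MNLS) stage reproduces the computational
skeleton of distributed source analysis on a deliberately small forward
model: `make_toy_leadfield()` builds an identity, random full-rank, or
ring-geometry gain matrix (sensors on an outer ring, fixed-orientation
scalar sources on an inner ring, gain decaying with distance). The
inverse operator is W = L&#8242;(LL&#8242; + &lambda;I)⁻¹; with
&lambda; = 0 and consistent data it returns the minimum-Euclidean-norm
exact solution (verified against a brute-force oracle over the solution
affine subspace), and as &lambda; &rarr; 0 it converges to the
Moore–Penrose pseudo-inverse. The default regularization,
&lambda; = trace(LL&#8242;)/n&#8203;<sub>sensors</sub> &times; 0.01, is a
mild fraction of mean sensor power — the original analysis software does
not expose its value, so the toy stage claims structural fidelity only.
"Source strength" is the magnitude of the estimated scalar current; there
is no depth weighting or noise-covariance whitening. Sensor repositioning
follows the two-step transform x&#8203;<sub>canon</sub> =
L&#8203;<sub>canon</sub> W&#8203;<sub>ind</sub> x&#8203;<sub>ind</sub>;
with the individual array modelled as the canonical ring rotated by half
a sensor spacing, the transfer error is below 1 %.

## Validation design and problem sizes

The test suite asserts three kinds of facts. *Exact identities*:
noise-free recovery of every injected delta through the full chain,
window sample counts, the corrected-alpha closed form, hand-enumerated
split assignments. *Oracle agreements*: ANOVA versus `aov`, epsilon
versus its eigenvalue form, minimum-norm versus brute force.
*Statistical properties at the study's scale* (22 subjects, 6 &times; 180
trials per task): across 50 simulated cohorts the scan must detect the
early interaction and late color windows in at least 90 % of cohorts; on
200 effect-free cohorts the per-window false-positive rate must stay
within two binomial standard errors of the corrected alpha (the
consecutive-samples rule makes whole-interval false alarms rare; their
empirical rate is reported, not asserted); across 50 cohorts the fast
median-split bin must carry the more negative early DC amplitude in at
least 90 %; and the repetition split must recover the injected 40 ms
benefit within three standard errors. The detection and null suites run
on the condition-average generator path (exact, as argued above); the
split suite runs the trial-level chain including artifact rejection.
Unit tests use miniature designs (2 blocks of 40–80 trials, 2–4
subjects) so the default suite completes in minutes.

`scripts/acceptance.R` recomputes all of these quantities from scratch
with a caller-supplied seed and additionally runs one full default-scale
pipeline, reporting the detected onsets, rejection fraction and split
interaction p-value it produced.

## Known limitations

Simulated subjects differ only by measurement noise — there is no
between-subject variance component on the effect amplitudes, which makes
group statistics somewhat cleaner than real cohorts. The epoch-level
generator draws noise independently per epoch, so it cannot exhibit
overlap or serial correlation between adjacent trials (the
continuous-recording path shares this limitation across epochs but not
within the ISI). The source stage is structural: its geometry, scale and
regularization are toys, and no anatomical claim survives contact with a
real head model. Finally, the sliding-scan aggregation (window mean) is
one of two defensible readings of a "three-sample window" test; the
alternative — requiring all three samples individually significant — is
stricter and can be emulated with `window_samples = 1` plus the run-length
rule.
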