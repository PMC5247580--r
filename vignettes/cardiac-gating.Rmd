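---
title: "Cardiac-cycle gating: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-cycle gating: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cardiogate` implements, end to end, the methodology of cardiac-cycle-gated
stimulus presentation: predicting the next R-wave online, aiming stimulus
onsets at fixed post-R offsets, re-coding trials a-posteriori by where the
stimulus actually landed in the cycle, and analysing the resulting
behavioural data with signal-detection, process-dissociation and
within-subject ANOVA machinery. This vignette documents the models behind
each stage, the parameters that matter, and the design choices made where
the methodology itself leaves room.

## The gating problem

Baroreceptor afferent traffic peaks during and shortly after ventricular
systole and is minimal between beats. To present a stimulus during one of
those states it must be timed relative to the R-wave — but when a mask or
background image must *precede* the stimulus, presentation has to begin
before the reference R-wave has occurred, so the beat's time must be
predicted. Prediction from a handful of preceding beats is imperfect
(heart rate fluctuates), so after the fact each trial is re-coded by the
measured onset-to-preceding-R latency:

* **systole**: latency in [200, 400] ms,
* **diastole**: latency in [450, 800] ms,
* **excluded**: [0, 200) ms (risk that the following stimulus overlaps the
  systolic window), (400, 450) ms (too ambiguous to classify) and
  (800, ∞) ms (beyond a plausible cycle).

Both classification windows are treated as *closed* intervals. The
methodology is usually described without a boundary convention; including
the endpoints maximises retained trials, changes classification only on a
measure-zero set of integer latencies, and is configurable through
`phase_windows()`.

## Heart rhythm model

Real studies record ECG; the package instead simulates R-wave series so
that every downstream stage is testable without participant data. The
inter-beat intervals follow a stationary Gaussian AR(1) process,

IBI_k = μ + x_k,  x_k = φ·x_(k−1) + ε_k,  ε_k ~ N(0, σ²(1 − φ²)),

so the marginal SD equals the nominal SDNN σ for any admissible φ, with an
optional additive sinusoid (amplitude in ms, frequency in Hz) emulating
respiratory sinus arrhythmia. Defaults — mean IBI 850 ms (≈71 bpm), SDNN
30 ms, φ = 0 — are typical resting values for healthy young adults, the
population such studies sample. Generated IBIs are clamped at a 300 ms
physiological floor and the clamping rate is reported; at the defaults it
is zero.

This is the simplest process with tunable SDNN and short-range
autocorrelation. It deliberately omits features of real ECG: 1/f
variability, ectopic beats, posture and task-evoked heart-rate changes
(e.g. deceleration after feedback), and any coupling between behaviour and
heart rate. Passing tests therefore demonstrate correctness of the
pipeline under a clean rhythm, not robustness to arrhythmia or artifact —
real recordings should be cleaned before entering `run_closed_loop()` or
`prediction_error_profile()`.

## Prediction and closed-loop scheduling

The online rule is rebuilt literally from its description: from the three
preceding R-wave times, form the two IBIs and extrapolate the next beat at
the last time plus their arithmetic mean (`predict_next_r()`, strategy
`"mean"`). The original implementation might instead have used three IBIs
from four beats, or weighted recent intervals more; both are available as
strategies (`"mean"` on four times, `"weighted"`), but the two-IBI mean is
the default as the most literal reading of "three preceding R-waves".
Under i.i.d. Gaussian IBIs with SD σ the signed prediction error has SD
σ·√(3/2) ≈ 36.7 ms at σ = 30 — which is exactly the spread the onset
latency distributions inherit, and why a ±100/±50 ms recoding margin keeps
exclusions in the low single digits.

`run_closed_loop()` replays the session: each inter-trial interval lasts
as long as it takes to detect four fresh heartbeats; the fourth triggers
the prediction; the stimulus is presented at predicted R + 300 ms
(systole-intended) or + 500 ms (diastole-intended). The emulated online
detection latency (default 1 ms, bounded by the ~2 ms hardware figure)
delays the *scheduling moment* but not the R-referenced onset, and the
trial's latency is measured to the nearest preceding **actual** R-wave —
including a beat that arrived earlier than predicted — because that is
the quantity the a-posteriori recoding uses. Whether the original
software re-predicted when an unexpected beat arrived before the
scheduled onset is not documented; the simulator does not, it simply lets
the recoding catch such trials.

## Task designs

Three canonical designs ship as `design_spec()` presets, each a fully
within-subject 2 (prime/race) × 2 (object) × 2 (phase) factorial:

| | WIT | FPST | SFIT |
|---|---|---|---|
| objects | tool / weapon | unarmed / armed | fruit / sport object |
| gated stimulus | prime (200 ms) | target (200 ms) | prime (200 ms) |
| target duration | 150 ms | — | 150 ms |
| deadline / collection | 500 / 650 ms | 650 / 1000 ms | 500 / 650 ms |
| trials per cell | 33 (264 total) | 23 (184 total) | 33 (264 total) |

The shooter task's published description ("180 trials, 23 per condition")
is arithmetically inconsistent — 8 cells × 23 = 184. The per-cell count
is taken as primitive and the total derived (184); `trials_per_cell` is
configurable if 22/23 mixtures are wanted. FPST payoffs are +10 (shoot
armed), +5 (don't shoot unarmed), −20 (shoot unarmed), −40 (don't shoot
armed), −10 (no response by the 650 ms deadline); responses between the
deadline and the 1000 ms collection bound score as timeouts, because the
online feedback used the deadline.

## Behavioural generator

Responses are Bernoulli per cell with a lognormal latency model
(moment-matched to `rt_mean`/`rt_sd`, defaults 420/80 ms) and an
independent no-response probability (`miss_rate`, default 0.02). A
response counts as on time when it exists and its latency is within the
collection window; accuracy is on-time correct responses over cell
trials, so late and absent responses depress accuracy — matching the
accuracy definition used with such tasks.

One modelling decision deserves emphasis: the generator keys `p_correct`
on the **recoded** phase, not the intended one. The hypothesised
mechanism is physiological — what matters is where the stimulus actually
fell in the cycle — so a diastole-intended trial that lands at 350 ms
must behave like a systole trial. A consequence is that recoded-cell
accuracies converge exactly to the generating `p_correct`, which is what
the parameter-recovery tests verify. Excluded trials draw from the
phase-average probability of their prime × object cell; they are dropped
before analysis regardless.

`p_correct_cells()` encodes three regimes around a `baseline` (default
0.85, the centre of the accuracy range such tasks produce): a
congruency gap confined to systole (`"systolic_bias"`, gap 0.09), the
same gap at both phases (`"phase_invariant"`, gap 0.05), and `"null"`.
The systolic gap of 0.09 was chosen so that a 30-subject cohort yields a
three-way interaction of the order of magnitude reported for
threat-stereotype tasks (F in the tens with η² ≈ 0.5), given the
per-cell binomial sampling noise of 33 trials; the phase-invariant gap of
0.05 likewise produces a clearly detectable two-way prime × object
effect. These are generator conditions fixed in advance of any testing,
not tuning knobs.

`simulate_cell_counts()` exposes the cell-level marginal of the full
generator (independent binomials per subject × cell). The calibration
studies — type-I-error rate of the three-way interaction over 2000
replicate cohorts, and rejection rates over 200 replicates per effect
regime — use this fast path, since the gating stage contributes nothing
to those statistics; the equivalence of the two paths is itself under
test via parameter recovery through the full pipeline.

## Indices

**SDT.** Hits are correct responses to the task's signal object (weapon /
armed / sport object), false alarms are errors on the noise object; d′ =
z(H) − z(F) and C = −(z(H) + z(F))/2. Error rates are 1 − accuracy, so
misses count as errors, consistent with the on-time accuracy definition;
whether the original analyses excluded misses from false alarms is not
documented. Extreme rates are corrected before the probit transform; the
default replaces 0 with 1/(2N) and 1 with 1 − 1/(2N) (the most common
convention), with a log-linear alternative (`(count + 0.5)/(N + 1)`,
applied to all rates) selectable. The published analyses do not state
their correction; at 33 trials per role the choice moves d′ by a few
hundredths only when a subject is at ceiling.

**PDP.** Per prime and phase, control = congruent-cell accuracy minus
incongruent-cell error rate, and automatic = incongruent error rate /
(1 − control). Control = 1 makes the automatic estimate undefined; it is
returned as `NA` and the affected ANOVA is reported as unavailable rather
than silently imputed. Under the generating process model (respond via
control with probability c, otherwise express an automatic bias a) these
estimators recover c and a exactly in expectation, which the tests verify
by simulation at 10⁵ trials.

## Inference

All factors have two levels, so the repeated-measures ANOVA is computed
exactly through ±1 difference contrasts: for effect contrast c and
subject scores L_i = Σ_j c_j y_ij, SS_effect = (Σ L_i)²/(8n), the error
term is the effect-by-subject interaction SS = Σ(L_i − L̄)²/8 with
df = n − 1, and F = t² of the per-subject difference score. Sphericity is
trivially satisfied with two levels, so no correction is applied — the
df are always (1, n − 1). Accuracies enter untransformed (no arcsine), as
is standard for these tasks. Partial η² = SS_effect/(SS_effect +
SS_error). The test suite checks this implementation against two
independent routes: a brute-force inclusion–exclusion sums-of-squares
oracle and base R's `aov()` error-strata decomposition.

Planned comparisons are classical paired t-tests with paired Cohen's
d = mean difference / SD of differences. Post hoc comparisons use the
Newman–Keuls stepwise studentized-range procedure over rank-ordered
condition means. Its error term is not standardised anywhere; the package
pools the condition-by-subject mean square from the one-way
repeated-measures ANOVA of the means under comparison (df (n−1)(k−1)),
and enforces the stepwise stopping rule by assigning each pair the
maximum range-test p over all spans containing it — so nested
comparisons inherit non-significance and corrected p never falls below
the pair's own range p. With two means the procedure collapses to the
paired t (q = t√2). Holm-corrected pairwise t-tests are available as a
more conservative alternative.

## Numerical and degenerate-case conventions

* Times are milliseconds throughout; I/O tables round to integer ms,
  internal computation keeps full precision.
* Zero-variance difference scores: t = 0, p = 1 when the mean is also
  zero; an infinite t with a warning otherwise — never a silent NaN.
* A detector finding no beats returns an explicit empty series with a
  warning; an exhausted heartbeat stream yields a flagged, truncated
  trial table.
* Cells emptied by exclusion surface as `NA`, not 0, and ANOVAs refuse
  incomplete designs naming the offending subjects.
* Cohort, heartbeat and cell-count generators are deterministic under
  their `seed` arguments.

## Problem sizes used by the shipped checks

The packaged test suite and acceptance script run at study scale where it
matters and at reduced scale where only algebra is being verified: the
exclusion-rate study uses the full 30 × 264 closed-loop simulation;
SDNN/autocorrelation recovery uses 10⁴–2×10⁴ beats; type-I calibration
uses 2000 replicate 30-subject cohorts at the cell level; the effect
regimes use 200 replicates each; PDP recovery uses 10⁵ trials. These
sizes give Monte-Carlo error comfortably inside the asserted bands.

## Known limitations

* The heart model is stationary; drift, arrhythmia and behaviourally
  coupled heart-rate changes are out of scope, as is raw ECG morphology
  (the threshold detector is exercised on toy impulse traces only).
* The fixed recoding windows are an operational definition of systole
  and diastole; no attempt is made to individualise them (e.g. from the
  QT interval).
* Reaction-time analyses, interoceptive-accuracy covariates and
  implicit-attitude correlates are not implemented.
* The Newman–Keuls error term and the SDT extreme-rate correction follow
  documented package conventions (above) where the original analyses are
  underspecified; both are configurable.
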