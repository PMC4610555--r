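---
title: "Gait-phase detection with continuous HMMs: models, training protocols and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase detection with continuous HMMs: models, training protocols and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gaitphase` segments pediatric treadmill walking into gait phases from the
sagittal angular velocity of the foot and the shank, using continuous
Gaussian-emission hidden Markov models. This vignette explains the model, the
two training protocols, the transition-based evaluation, the synthetic cohort
generator, and the numerical and design choices behind them.

## The problem and the signals

A gait cycle (stride) runs from one heel contact to the next of the same
foot. Three nested phase vocabularies are supported:

* **2P** — stance (SP) and swing (SW);
* **4P** — flat foot (FF), heel off (HO), swing (SW), heel strike (HS);
* **6P** — initial contact (IC), loading response (LR), mid stance (MS),
  terminal stance (TS), pre swing (PS), swing (SW).

Two signals are available per trial: the sagittal angular velocity (deg/s,
50 Hz) of the instrumented foot and shank. The reference segmentation comes
from four binary footswitches (heel, 5th and 1st metatarsal heads, toe;
200 Hz): each combination of pressed switches maps to a phase (`phase_model()`
encodes the truth table, e.g. heel alone is IC in 6P, all four pressed is FF
in 4P, no switch is swing everywhere). Combinations outside the table are
resolved in tiers: a unique most-specific subset match first (so all four
switches pressed resolves to MS in 6P), otherwise the previous phase is held.
A specificity *tie* (e.g. heel+toe in 6P, matching IC and PS equally) also
holds the previous phase, since such combos are transient sensor states with
no phase identity of their own.

## The classifier

Each phase is one HMM state with a univariate Gaussian emission (mean and SD
in deg/s). The transition matrix is **left-right and cyclic**: a state may
persist or step to the next phase in cycle order, and the last phase wraps to
the first, because a trial spans dozens of uninterrupted cycles. Self-
transition probabilities are initialized from mean phase durations as
`a_ii = 1 - 1/d_i`. The initial distribution is uniform — the phase at trial
onset is unknown. The model container carries a mixture-weight matrix so that
multi-component emissions are representable, but the default (and tested)
configuration is one component per state, the minimal faithful reading of a
Gaussian-mixture cHMM when no mixture count is prescribed.

Decoding is exact offline Viterbi in log space; per-sample state posteriors
come from the forward-backward recursion on the same observations. A
fixed-lag variant (`fixed_lag_viterbi()`) emits the best-path state `lag`
samples behind the current input and reduces exactly to the offline path when
the lag reaches the sequence length; it exists because online control
applications cannot wait for the trial end. The offline decoder is the
default everywhere.

The **scalar classifier (SC)** decodes one segment's signal. The
**distributed classifier (DC)** fuses the foot and shank scalar classifiers:
per-sample posteriors are combined convexly (`s_j = w_ft γ_ft,j + w_sh γ_sh,j`,
uniform weights by default) and the fused scores are decoded through a
"right-left-right" transition matrix `A_dc` that permits self, next *and
previous* phase steps (cyclic tridiagonal, stay probability 0.9), so the
fusion stage can retract a premature member transition. The exact fusion rule
behind the published distributed classifiers is not fully specified in the
open literature; the convex-posterior rule decoded through `A_dc` is this
package's explicit reconstruction, and an optional performance weighting
(`w_k ∝ √2 − G_k` on the training data) is exposed in `study_config()`.

## Training protocols

Both protocols are supervised-then-refined:

1. the footswitch reference partitions the filtered training signal;
2. every phase occurrence is time-normalized to `L_norm = 100` samples by
   linear interpolation, so long and short occurrences weigh equally; the
   pooled ensemble gives each phase's emission mean and SD, and mean raw
   durations give the transition matrix;
3. Baum-Welch refines all parameters (log-space recursions, structural
   zeros preserved, variances floored).

**SST (subject-specific training)** uses the subject's own repetition 1 of a
condition and is evaluated on repetition 2.

**SPT (standardized-parameter training)** replaces the subject's data with a
healthy-cohort template: every typically developed (TD) subject's
repetition-1 cycles are time-normalized to `L_cycle = 200` samples, averaged
within subject, then across subjects. For TD evaluation the evaluated subject
is left out of the template (leave-one-out); for the hemiplegic (HC) group
the template uses all TD subjects. The template's phase script is the
majority vote of the included subjects' normalized reference labelings, and
whole cycles are averaged first and partitioned afterwards (the alternative
order — partition first, average per phase — discards the within-cycle
timing structure the transition matrix is initialized from).

Two SPT choices deserve emphasis:

* **Template dispersion.** The emission SD of an averaged waveform would be
  far too small — averaging shrinks variance, and an unseen subject deviates
  both as a subject (between-subject spread of means) and stride by stride
  (within-subject variance). The template therefore carries, per normalized
  time point, `sd = sqrt(var_between(subject means) + mean(var_within))`,
  pooled per phase into the emission SDs.
* **Refinement floor.** Baum-Welch refinement runs on `spt_cycles = 10`
  concatenated template cycles, which are nearly noise-free; unconstrained
  re-estimation would collapse the variances onto the averaged waveform and
  discard the dispersion just constructed. Refinement therefore floors each
  state's variance at its dispersion-informed initialization, so it can
  re-center means and durations but never become overconfident.

## Preprocessing

Angular velocities are low-pass filtered with a Butterworth filter at 15 Hz.
The order (4) and the zero-phase forward-backward application are this
package's choices: a causal filter delays every waveform feature by several
milliseconds, which would bias all detected transitions late — intolerable
when the evaluation window is ±30 ms. The footswitch trace is aligned to the
gyro time base by taking the state of the nearest 200 Hz sample at each
50 Hz timestamp, which preserves binarity and onset timing to ≤ 2.5 ms;
reference sequences are produced at the gyro rate so prediction and
reference share one time base.

## Evaluation

The positive event is the **phase transition**. A reference transition is a
true positive if a predicted transition with the identical (from, to) phase
pair lies within a 60 ms window centered on it; matching is greedy
nearest-first and one-to-one. Unmatched reference transitions are false
negatives, unmatched predictions false positives, and every remaining
non-transition sample a true negative. At 50 Hz the 30 ms half-window is
1.5 samples, rounded down to ±1 sample (`tolerance_halfwidth()`): the
stricter reading of an ambiguous rounding, and the one under which a
one-sample shift is still a hit. From TPR and TNR the goodness index

$$G = \sqrt{(1-\mathrm{TPR})^2 + (1-\mathrm{TNR})^2}$$

is the Euclidean distance to the perfect corner of ROC space: `optimum`
at G ≤ 0.25, `good` up to 0.70, `random` at 0.70 (= √2/2, a chance-level
classifier), `bad` beyond. Note the attainable maximum is √2, not 2: the
distance from (TPR, TNR) = (0, 0) to (1, 1). Zero-denominator rates are
reported as `NA` and excluded from aggregation with a warning, never
silently treated as zero. `run_study()` crosses the 18 classifier
configurations — {SST, SPT} × {2P, 4P, 6P} × {foot SC, shank SC,
foot+shank DC} — with every subject and condition, training on repetition 1
and evaluating repetition 2, and `aggregate_study()` reports mean ± SD of G
per group × condition × classifier cell.

## The synthetic cohort generator

No recordings ship with the package; `generate_cohort()` produces
phase-structured cohorts so the full study design is exercisable end to end.
A `gait_template()` fixes cadence (35 strides/min — slow treadmill walking
at 1.0 km/h), 6P phase duration fractions (IC 0.04, LR 0.12, MS 0.19,
TS 0.15, PS 0.10, SW 0.40 — plausible for slow pediatric gait; no published
tabulation exists at these speeds, and the values are config-exposed), and
per-phase waveform levels interpolated by monotone cubics. The waveforms are
stylized, not recordings: each phase holds a characteristic level anchored
just inside its boundaries, with interior shape points for the swing peaks
(double-peaked for the shank) and a sharp swing-initiation surge whose onset
slightly precedes toe-off, mirroring how the real push-off velocity spike
develops before the toe leaves the ground. A mid-stance step coincides with
the toe-switch onset, since toe contact accompanies the forward shift of
load during foot-flat. The footswitch script follows the progression
{heel} → {heel,m5} → {heel,m5,m1} → {all four} → {m5,m1,toe} → {toe} → {},
and the emitted phase script is *derived from those combos through the
package's own partitioning rules*, so generator and partitioner agree
exactly by construction on noise-free trials — the consistency oracle used
throughout the tests. A `strict_switches` mode emits only exact-rule combos.

Variability has three layers: between subjects (cadence and amplitude scale,
SD 5% and 10%; phase-fraction perturbation), between strides (timing SD 3%
and amplitude SD 10% for TD — stride-to-stride amplitude variation of about
10% is typical of children — doubled timing and 18% amplitude for HC,
reflecting the higher intra-subject variability of hemiplegic gait; HC
additionally carry wider between-subject timing spread), and additive
sensor noise (2 deg/s). Conditions modulate the template: the faster speed
raises cadence and amplitude by 25%/10%, incline raises shank amplitude by
15%. A 3-axis mode adds frontal/transverse components so
`perturb_rotation()` can emulate IMU mounting error by rotating the
angular-velocity vector a few degrees and re-extracting the sagittal axis.

What the generator does **not** emulate: soft-tissue artifact, footswitch
bounce or partial activation, non-stationary fatigue drift, asymmetric
bilateral coupling, or genuinely pathological waveform *shapes* (HC subjects
differ statistically, not morphologically). Passing tests therefore
demonstrate that the pipeline is correct and behaves sensibly under the
emulated variability — not that these G values would be attained on real
recordings.

## Numerical choices

* All HMM recursions run in log space with max-shift scaling; emission
  log-densities are floored at `log(1e-300)`, so an observation improbable
  under every state can never produce NaN.
* Baum-Welch stops at a relative log-likelihood change below `1e-6` or at
  the iteration cap; within the training protocols the cap is 30 iterations,
  which supervised initialization makes ample (the generic `baum_welch()`
  default is 100).
* Variance floors default to `1e-4 ×` the training-signal variance; a
  zero-variance phase (constant signal) receives the floor rather than a
  degenerate Gaussian.
* Evaluation half-windows round half-down (1.5 → 1 sample), the stricter
  alternative.
* The study sizes used by the acceptance script and the heaviest test —
  10 TD + 10 HC subjects, 4 conditions, 2 repetitions of 30 s at 50 Hz —
  are the package's scaled-down rendition of the emulated study design
  (which used ≥ 60 s trials); 30 s spans ~17 strides per trial, enough for
  stable phase statistics while keeping a full 18-classifier factorial run
  in minutes on one CPU.

## Known limitations

* Emissions are univariate and instantaneous; no derivative or windowed
  features, so phases distinguished only by signal dynamics (not level)
  would confuse the model.
* The fusion rule is a reconstruction (see above); other weighted
  hierarchical decisions are plausible.
* The fixed-lag decoder is provided but not used in the study protocol; the
  exact "modified Viterbi" of the original real-time implementations is not
  reproducible from the open description, so the package offers the exact
  offline decoder plus a principled online variant and records which was
  used in model metadata.
* `transition_confusion()` counts negatives per non-transition sample, the
  natural sample-level reading of a per-time-step tolerance window; an
  event-level negative definition would change TNR (though barely, since
  non-transitions dominate) but not TPR.

## A worked example

```{r, eval = FALSE}
library(gaitphase)

cohort <- generate_cohort(list(
  cohort_spec(n_subjects = 10, group = "TD", duration_s = 30, seed = 1),
  cohort_spec(n_subjects = 10, group = "HC", duration_s = 30)))

results <- run_study(cohort)
aggregate_study(results, group_by = c("procedure", "model_id", "signal"))
```

The per-classifier means of G on this seeded cohort all fall well inside the
good-to-optimum band; `scripts/acceptance.R` recomputes them from scratch,
together with the analytic chance-level anchor G(0.5, 0.5) = √2/2 ≈ 0.71.
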