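---
title: "Phase-gated locomotion-mode recognition: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-gated locomotion-mode recognition: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science inside **gaitmode**: the recognition
model and its assumptions, the synthetic gait generator and what it does
and does not emulate, the numerical choices, and the design decisions
taken where the problem was genuinely open.

## The recognition problem

A powered lower-limb prosthesis must know the wearer's locomotion mode —
standing (S), level walking (W), stair ascent/descent (SA/SD), ramp
ascent/descent (RA/RD) — and ideally must know it *before* the leg
commits to new terrain. The input is a 20-channel, 100 Hz stream: four
plantar-pressure channels per insole on both feet, and pitch, roll and
two accelerations for thigh, shank and foot of the instrumented
("measured") leg, which stands in for the prosthetic side.

All signals are quasi-cyclic and phase-dependent: a thigh-pitch value
that is normal in swing is anomalous in double stance. The package
therefore uses a two-level strategy. The first level segments the gait
cycle into four adjacent phases from both insoles — initial double
stance (DS1), single stance (SS), terminal double stance (DS2), swing
(SW), anchored on the measured leg. The second level routes each
analysis window to a phase-specific linear discriminant classifier.
Restricting each classifier to one quarter of the cycle removes most of
the within-class variance that phase mixing would otherwise cause.

## First level: contact and phases

Foot contact is hysteresis thresholding of the lightly smoothed
4-sensor sum: contact begins above `theta_on` and ends below
`theta_off`. The defaults (0.30 and 0.15) are fractions of the nominal
single-support stance sum, which is ~1 in the package's normalized
pressure units. Fixed absolute thresholds were chosen over per-trial
calibration for two reasons: an online system cannot look at the whole
trial before deciding (causality), and with rectified sensor noise a
trial-level "median stance" statistic is dragged toward the standing
level, producing unsafe thresholds. Debouncing is a refractory period
(default 50 ms) rather than persistence confirmation, so genuine events
are timed with zero lag — on noise-free simulation, detected events land
within one sample of ground truth.

The phase machine's triggers are: measured foot-contact starts DS1,
contralateral foot-off starts SS, contralateral foot-contact starts DS2,
measured foot-off starts SW. Measured-leg events always dictate the
state; a contralateral trigger that contradicts the measured foot's
state is logged and the state held. With no new events (standing), the
current double-stance state persists — which is why every phase
classifier sees standing windows and can recognize standing in any
phase.

## Second level: windows, features, classifier

Analysis windows are right-aligned (the decision's timestamp is its last
sample), 150 ms long by default, advancing one 10 ms sample at a time;
sizes 100–200 ms are supported for sweeps. A window overlapping a
ground-truth mode boundary is labeled with the earlier mode only if
strictly more than half of its samples precede the boundary; an exact
split goes to the later mode (the same rule labels phases). Mode
boundaries are placed by fixed rules: leaving standing, the instant
either foot leaves the ground; entering standing, the final swing-leg
contact; all other transitions, the midpoint of the swing of the leg
that first left the previous terrain.

Each window yields six time-domain features per channel: maximum,
minimum, mean, waveform length (the sum of absolute successive
differences), standard deviation and RMS. The standard deviation uses
the population (divide-by-n) form so that `rms^2 = mean^2 + std^2` holds
exactly — a free self-consistency invariant used by the tests. Features
are z-scored with training-set statistics stored in the model, making
predictions invariant to any affine rescaling of the raw channels; this
matters because pressures, angles and accelerations live on different
scales.

The classifier is linear discriminant analysis: per-class means, a
pooled within-class covariance `Sigma_hat` with `M - K` degrees of
freedom, shrinkage `(1 - lambda) * Sigma_hat + lambda *
(tr(Sigma_hat)/d) * I`, and class posteriors as a softmax over the
linear discriminant scores. The default `lambda = 1e-3` exists because a
120-dimensional covariance estimated from a few thousand overlapping
windows can be close to singular; at this size the shrinkage changes
decisions negligibly while guaranteeing a positive-definite matrix.
Classes absent from a phase's training data are simply absent from that
phase's model. On small well-conditioned problems with `lambda = 0` the
implementation agrees decision-for-decision with a brute-force
pooled-covariance Gaussian Bayes classifier (and with `MASS::lda`).

## Post-processing

Raw decisions are smoothed by a posterior-weighted majority vote over
the last `N = 5` decisions: weight `(p - p0)/(1 - p0)` above the
posterior threshold `p0 = 0.5`, zero below; the output switches to the
top-voted mode only when its voting value strictly exceeds
`gamma * N = 3.75`, and otherwise holds. Three consequences shape the
system's behavior: a single contrary decision can never flip the output;
a mode change at full confidence is adopted once 4 of the 5 buffered
decisions carry it (about 40–50 ms); and low-confidence errors do not
vote at all. Before the buffer fills, the output is the most recent raw
decision, which also seeds the held value — the equations need a
previous decision and the data offer none better. An exact tie between
top-voted modes is treated as not exceeding the threshold (hold), the
conservative reading of the hold rule. The unweighted 15-decision
plurality (ties hold) is implemented as the comparison baseline; on
bursty noisy decision streams the weighted vote yields both fewer steady
errors and earlier transition switching, which is the point of weighting
by confidence.

## Transition scoring

Transition periods start at the leading leg's foot-off (or, leaving
standing, when either foot lifts) and end at the next single-stance
onset after the official boundary; entering standing, the period is
exactly the final swing. The critical moment is the measured foot's
first contact in the period — or the final contact itself when stopping
— i.e. the deadline by which a prosthesis controller must have switched.
Detection requires more than 30 consecutive decisions (>= 31 at 100/s)
of the new mode starting inside the period, with no contrary decision
later inside the period; the qualifying run may finish after the period
ends, since a late detection is late, not absent. Prediction time
`T_pre = t_c - t_pre` is negative for late detections; a missed
detection costs a fixed 2000 ms in the adjusted prediction time. Where
several runs could qualify, the earliest is scored; undetected
transitions contribute only the penalty term.

One structural consequence deserves note: advance detection *requires*
the smoothed stream to read "standing" while the last pre-boundary
windows are still labeled "walking" (the majority rule keeps labels on
the old mode until half the window has crossed). Every correctly
predicted stop therefore contributes about half a window of W-labeled,
S-predicted decisions just after the critical moment. These show up as a
small walking-to-standing entry in the steady confusion matrix — they
are the price of predicting early, not classifier mistakes.

## The synthetic gait generator

No public dataset provides this sensor suite with labeled transitions,
so the package generates one. `default_protocol()` reproduces a ~40 s
protocol trial: stand, walk, stair ascent, walk, ramp descent, walk,
stand/turn/stand, walk, ramp ascent, walk, stair descent, walk,
stand/turn/stand — each of the ten transition types at least once,
stand-to-walk and walk-to-stand twice. Set-A trials let the measured leg
lead the transitions S→W, W→SA, SA→W, W→RD, RD→W and W→RA; Set-B mirrors
the assignment. Turn-backs are dynamic standing: small alternating steps
(quarter amplitude) flanked by static standing, all one standing
segment.

The signal model is deliberately simple — the pipeline only needs
quasi-cyclicity, phase structure and controllable separability:

* **Timeline.** Steps alternate legs with the configured phase
  fractions (DS1/SS/DS2/SW = 12/38/12/38% of a 1.1 s cycle by default);
  foot-contact and foot-off events, official mode boundaries and mode
  segments are derived exactly from this timeline, so ground truth is
  exact by construction.
* **Pressure.** Each stance is a heel-then-forefoot sequence of smooth
  bumps with steep loading/unloading edges (so detected events land
  within a sample of truth) ending on a mode-independent push-off
  plateau; ascent loads the forefoot, descent the heel, standing loads
  both feet at half weight. Landings during a deceleration to standing
  blend toward the standing pattern and settle almost immediately.
* **IMU.** Each channel is a mode-dependent offset plus a sinusoid over
  the cycle, multiplied by an envelope that ramps in over a third of a
  cycle when locomotion starts and fades out before it stops. Stair and
  ramp siblings are deliberately close; their contrast is carried
  mostly on the low-amplitude roll channels, so separating them depends
  on averaging sensor noise over the window — which is what makes
  larger analysis windows genuinely better, as in real systems. The
  first stride onto new terrain is emphasized away from the sibling
  mode (a cautious, exaggerated entry step), keeping transition periods
  free of sibling flicker.
* **Variability and noise.** Per-subject channel offsets, amplitude and
  insole-gain factors (fixed per subject), small per-subject and
  per-trial mode-template jitter, stride-to-stride baseline wander
  (AR(1), 40 ms correlation), brief motion artifacts on one IMU module
  at a time, and white Gaussian sensor noise (`noise_sd`, in template
  units per channel scale). Wander and artifact amplitudes scale with
  `noise_sd`, so `noise_sd = 0` yields bit-reproducible, exactly
  periodic trials.

What the generator does **not** emulate: biomechanically realistic
kinematics or kinetics, ramp inclination or stair geometry as numbers,
sensor-fusion filtering (angles arrive already fused), EMG-style
long-term drift, or hardware effects such as packet loss. Passing the
end-to-end tests therefore demonstrates that the pipeline's logic,
timing and statistics behave as designed under controlled conditions —
not that the accuracy numbers transfer to any particular physical
dataset.

## Evaluation design

Classifiers of this kind are user-trained, so cross-validation is
subject-specific: for each synthetic subject, each experiment pair (one
Set-A and one Set-B trial) is held out in turn and the bank trained on
the subject's remaining pairs, always pooling both variants — training
on a single variant transfers measurably worse to the other, which is
the reason for pooling. Headline metrics are averaged per subject and
reported with the SEM across subjects. The steady-period confusion
matrix is tabulated on the raw (pre-voting) classifier decisions, where
error structure is attributable to the phase classifiers; steady
accuracy and transition detection are scored on the smoothed stream,
which is what a controller would consume.

Problem sizes were chosen to keep a full evaluation comfortable on a
laptop: the standard cohort is 7 subjects x 6 pairs (84 trials, about
335,000 windows), cross-validated in well under a minute after feature
extraction, with window-size sweeps using a fixed 3-pair/3-pair split
and the training-amount sweep an 8-pair cohort with the last pair held
out.

## Known limitations

* Phase segmentation needs both insoles; a one-sided sensor set would
  require a different first level.
* The LDA bank shares one window size and feature set across phases; a
  per-phase choice could do better.
* The fully deterministic corner (`noise_sd = 0` with per-trial jitter
  forced to zero) makes nearly identical windows separable to machine
  precision, which can produce overconfident posteriors near mode
  boundaries; any realistic noise level removes the effect.
* Simulated difficulty is calibrated, not measured: absolute accuracy
  values on synthetic cohorts say nothing about hardware.
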