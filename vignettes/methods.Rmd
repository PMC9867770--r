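---
title: "Models and methods: IMU-based activity recognition and payload classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: IMU-based activity recognition and payload classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Occupational low-back exoskeletons need two pieces of high-level information
to modulate their assistance without any manual trigger: *what the wearer is
doing* (standing still, walking, or interacting with an object — and, within
interactions, lifting versus lowering) and *how heavy the handled load is*.
`exohar` implements a complete, testable pipeline for this task from five
body-worn six-axis inertial measurement units (chest, both wrists, both
thighs; 3-axis accelerometer in m/s², 3-axis gyroscope in deg/s, 100 Hz):
a seeded synthetic motion generator; zero-lag and causal low-pass filtering;
leakage-free min–max scaling; subject-specific multi-output LSTM classifiers;
a gated streaming cascade; and the evaluation and sensor-reduction statistics.

Everything downstream of the generator treats the recordings as opaque
labeled sensor data, so the same code paths run unchanged on real recordings
in the documented CSV dialect.

## The synthetic motion generator

The generator is a first-class, tested module, not a fixture. Each *subject*
is a draw of kinematic parameters (`make_subject_profile()`), each *session*
a protocol script rendered into a continuous 30-channel recording with
per-sample labels.

**Kinematic model.** Every sensor-bearing body segment carries one pitch
trajectory $\varphi(t)$ (degrees). The gyroscope's longitudinal-plane axis
measures $\dot\varphi$; the accelerometer measures gravity projected through
the pitch, $[g\cos\varphi,\; 0,\; g\sin\varphi]$, plus a tangential term
$\ell\,\ddot\varphi$ with a per-placement lever $\ell$ (wrists largest,
chest smallest), plus i.i.d. Gaussian noise per channel. This reduced model
reproduces the features the classifiers actually exploit — trunk-flexion
transients, gait oscillation, quiet standing — and nothing more.

**Actions.**

* *Stand*: all trajectories constant; the chest accelerometer reads gravity
  on its longitudinal axis.
* *Walk*: tapered sinusoidal thigh oscillation at the subject's gait
  frequency (antiphase left/right), small chest oscillation at twice the
  step frequency, light arm swing.
* *Lift / lower*: a skewed raised-cosine trunk-flexion bell — one
  flexion–extension arc per event. Lifts peak early in the segment (skew
  0.35), lowers late (0.65), and the wrist rotation changes sign between the
  two, so the interaction types are distinguishable even from the chest
  alone. On top of the bell, a sustained counterbalance lean proportional to
  the held mass (0.6°/kg at the chest, doubled at the wrists, tapered at the
  segment edges) keeps the payload observable throughout the interaction,
  as a held load biases posture for as long as it is in the hands.

**Payload dependence.** For a load of $w$ kg the interact-segment duration
scales as $d_0 (1 + c_s w)$ and the kinematic amplitude as $(1 + c_a w)$
(flexion depth scales with $c_a w / 2$). With the default parameter ranges
— $c_s \sim U(0.04, 0.07)$ per kg, $c_a \sim U(0.03, 0.05)$ per kg — the
three payload classes (5/10/15 kg) are statistically separable but overlap
under the per-repetition jitter (coefficient of variation $U(0.04, 0.08)$
applied to every repetition's durations and amplitudes), which is what makes
classification realistic rather than trivial. A threshold on mean lift
duration separates 5 from 15 kg perfectly when noise is disabled (a tested
invariant); windowed classifiers at default noise land well below perfection.

**Noise and difficulty.** Default accelerometer noise is $U(0.2, 0.4)$ m/s²
and gyroscope noise $U(2, 5)$ deg/s per subject — intentionally far above
instrument-grade IMU noise, because in this generator the noise term also
stands in for every real-world disturbance the kinematic model omits
(soft-tissue artifact, strap slip, off-plane motion). A global
`noise_scale` multiplier controls difficulty without touching the kinematics.

**Labels and transitions.** Segment trajectories start and end at rest
*inside* their segment, so all transition dynamics fall on the samples of
the upcoming activity: every transition is assigned to the subsequent class,
and the labeled onset always precedes the kinematic peak. This favors prompt
detection — the consumer of these predictions (an exoskeleton controller)
needs the class at movement onset, not in hindsight.

**Protocols and datasets.** Protocol 1 (payload protocol): stand–lift–stand–
lower cycles, 10 repetitions per payload, pauses of 10 s by default. Protocol
2 (activity protocol): the fixed sequence stand → walk → lift → walk
(carrying) → lower → walk (return); carrying is labeled *walk* because the
interaction vocabulary is reserved for the lift/lower events themselves.
The published composition gives per subject: D1 = protocol 1 at all three
payloads; D2 = protocol 2 at 10 kg (10 repetitions); D3 = protocol 2 at all
payloads (2 repetitions each). The generator does not model the box-mass
arithmetic of the physical setup; nominal class weights are used.

**Seeding.** All randomness descends from one integer study seed through a
documented splitting function (`derive_seed()`); per-subject and per-dataset
seeds stay below $2^{31}$. Identical seeds give byte-identical CSV output.

What the generator does **not** emulate: true lifting biomechanics (no
squat/stoop distinction, no multi-joint coordination), magnetometer
channels, sensor drift or dropout, or realistic walking ground impacts.
Passing recovery tests on this data shows the pipeline is correct and the
architecture adequate for kinematics whose class structure resembles the
modeled one — it does not certify performance on any particular real cohort.

## Preprocessing

* **Zero-lag filtering (offline).** A 4th-order low-pass Butterworth at 5 Hz
  (the bandwidth of voluntary human movement), designed by `signal::butter()`
  and applied forward–backward. "Fourth-order, zero-lag" is read as a
  4th-order *design* applied twice (the common implementation of the
  phrase), giving an effective 8th-order magnitude response and exactly zero
  phase. Edges use odd-reflection padding of 3× the filter order with
  steady-state initial conditions, so constants pass exactly (unit DC gain)
  and the padding never leaks transients into the signal.
* **Causal filtering (online).** The same 4th-order design applied in a
  single forward pass through a direct-form-II-transposed kernel with
  explicit state. The batch causal filter and the one-sample streaming step
  share this kernel, so they are bit-identical by construction — a tested
  invariant, not an approximation.
* **Scaling.** Per-feature min–max to $[-1, +1]$, fit on training data only
  and applied unchanged to test and streaming data. No clipping:
  out-of-range values extrapolate linearly, preserving information.
  Degenerate (constant) features are rejected at fit time.
* **Sensor reduction.** Column subsetting in canonical order: 30 features
  (all five IMUs) → 18 (chest + thighs) → 6 (chest only).
* **Windowing.** Sliding windows of 100 samples (1 s at 100 Hz), labeled by
  their **last** sample. Stride 1 at evaluation (per-sample predictions at
  the 100 Hz rate); a larger training stride (default 4) thins the heavily
  overlapping training windows for speed without changing their
  distribution. 1 s covers the fastest lift onset while keeping the
  streaming buffer small.

## The classifiers

Both networks share the trunk *two LSTM layers → dense tanh layer → softmax
head(s)* on the final timestep's hidden state. The package defaults follow
the reference architecture: 100 and 50 recurrent units, 20 dense units; the
HAR model is multi-output with a 3-class action head (stand/walk/interact)
and a 2-class interaction head (lift/lower); the payload model has a single
3-class head (5/10/15 kg).

No deep-learning framework for R is assumed: the forward pass,
backpropagation through time, Adam, gradient clipping and early stopping are
implemented in the package's own RcppArmadillo code (`src/lstm.cpp`), seeded
explicitly (`std::mt19937`) so training runs are reproducible to the bit on
a fixed backend.

Training choices (the source architecture's description leaves these open;
all are package decisions):

* Masked categorical cross-entropy: the interaction head receives zero
  sample weight on non-interaction windows — those windows simply carry no
  lift/lower ground truth — and is excluded from interaction metrics. The
  two HAR head losses are equally weighted.
* Adam at learning rate $10^{-3}$, batch 64, at most 50 epochs.
* Early stopping on validation support-weighted F1 (patience 5), keeping the
  best epoch's weights. Validation holds out whole *repetitions* (~10%,
  stratified by payload), never random windows: adjacent windows overlap by
  $W - \text{stride}$ samples, so window-level validation would leak
  near-duplicates of training windows and inflate the stopping criterion.
* Prediction is argmax with lowest-index preference on exact ties.
* Recurrent state is reset per window (windows are processed independently);
  streaming statefulness lives in the filter and the circular buffer, not in
  the network.

Models are subject-specific, following the design they implement: inter-
subject lifting kinematics vary too much for a small pooled model, and a
per-wearer model can adapt to individual technique by construction.

**Splits** (at repetition granularity, stratified by payload, to prevent
leakage of temporally adjacent samples): HAR trains on all of D2 and tests
on all of D3; the payload model trains on 90% of D1 plus 50% of D3 and
tests on the remaining 10% of D1 plus 50% of D3. Repetition boundaries are
recovered from the label track itself, so the CSV format needs no extra
bookkeeping column.

## Gated streaming inference

At each 100-Hz step the raw sample is causally filtered, pushed into a
circular buffer of one window, and — once the buffer is full — the HAR model
runs. If and only if the predicted action is *interact*, the interaction
head is read and the payload model is invoked on the same window. No output
is emitted during buffer warm-up (the first $W-1$ samples): fabricating
dynamics by zero-padding would produce predictions from data that never
happened. The gate means the payload network runs only when its output is
meaningful to a controller, exactly as it would be deployed.

Two properties are enforced by tests rather than assumed: *gating soundness*
(no interaction/payload output ever accompanies a non-interact prediction)
and *stream/batch equivalence* (replaying a recording sample by sample
yields the same label sequence as the batch pipeline, which shares every
numerical kernel). Per-step latency is measured and reported by `replay()`
but never asserted against: it is a property of the host machine.

## Evaluation and the sensor-reduction comparison

Per class $c$: $\mathrm{Pr} = TP/(TP+FP)$, $\mathrm{Re} = TP/(TP+FN)$,
$F_1 = 2\,\mathrm{Pr}\,\mathrm{Re}/(\mathrm{Pr}+\mathrm{Re})$, and accuracy
$= (TP+TN)/(TP+TN+FP+FN)$, from one-vs-rest counts. "Weighted" scores
average per-class values with class-support weights (the convention implied
by the standard library metric of that name); macro averages are also
exposed. Ratios of the form $0/0$ are reported as 0 with an explicit
degenerate flag rather than raised. Per-subject score distributions are
summarized as Q1/median/Q3 with linear interpolation between order
statistics (`stats::quantile`, type 7).

The cascaded test protocol mirrors deployment: HAR heads are scored on D3
(the interaction head only on ground-truth interaction windows); the
payload model is scored on its test split restricted to windows *gated* by
the HAR model's own predictions (ground-truth gating is available as a
diagnostic mode; the two coincide for a perfect gate). Gated windows
without defined payload ground truth are counted and excluded.

Sensor configurations are compared pairwise on per-subject F1: Shapiro–Wilk
(α = 0.05) on the **paired differences** — the quantity whose normality the
paired t-test actually assumes — routes to the paired t-test or the
two-sided Wilcoxon signed-rank test; the Bonferroni-corrected value
$p^* = 3p$ is reported and significance declared at raw $p < 0.05/3 \approx
0.0167$. All-zero differences leave both tests undefined: flagged,
not significant.

## Desk-scale profile and problem sizes

The package's tests and acceptance checks run a *desk-scale* profile chosen
once as the package's own study conditions for fast, single-CPU runs: pauses
and stand/walk segments of 2 s (protocol composition, repetition counts and
payload sets unchanged), networks of 24/12 recurrent and 10 dense units,
training stride 4, evaluation stride 3, three synthetic subjects. The
paper-scale defaults (10-s pauses, 100/50/20 units, stride 1) remain the
package defaults for real use. Under the desk-scale profile a full subject
(two models) trains in about a minute on one CPU; held-out action F1 lands
around 0.90–0.97 and payload F1 around 0.80–0.90 at default difficulty,
degrading monotonically as the noise multiplier grows — these are exactly
the quantities the test suite recomputes, and no number is asserted that
the suite does not itself produce.

One desk-scale caveat worth knowing: with 2-s stand/walk segments and 1-s
last-sample-labeled windows, up to half of the stand- and walk-labeled
training windows are *transition* windows whose content mostly belongs to
the preceding activity. Classification errors therefore concentrate at
activity transitions, and small networks can blur the stand/walk boundary
on atypically long quiet stretches while leaving the interaction gate —
the output that drives the payload model — unaffected. At the paper-scale
10-s pauses the ambiguous fraction is small.

## Known limitations

* The generator's planar, single-angle kinematics cannot probe effects that
  depend on richer real-world structure (grasp style, asymmetric lifts,
  fatigue drift); conclusions about sensor reduction on synthetic data are
  about the pipeline's statistics, not about human movement.
* Payload output is a class, not a weight estimate; unseen intermediate
  loads map onto the nearest trained classes.
* The LSTM implementation is deliberately compact (no dropout, no stacked
  statefulness, single-threaded); it targets correctness and
  reproducibility over raw training speed.
* Whether the reference system's "fourth-order zero-lag" counts the per-pass
  or combined order, and its exact windowing for 100-Hz prediction, are not
  documented; the package fixes both choices explicitly (4th-order per pass;
  last-sample-labeled 1-s windows) and records them here.
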