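---
title: "Models and methods behind myoreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myoreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(myoreach)
```

## What the package models

`myoreach` simulates, end to end, a screen-based target-reaching experiment
driven by surface EMG (sEMG) of the forearm. Two classic real-time
myocontrol schemes are implemented over a shared signal pipeline:

* **Direct control (DC).** One antagonist wrist pair — flexor carpi ulnaris
  (FCU) and extensor carpi ulnaris (ECU) — drives one cursor axis at a time
  through the signed, MVC-normalized activation difference. A discrete mode
  switch (co-contraction of the pair, or a separate trigger muscle for users
  who cannot co-contract reliably) toggles which axis is active.
* **Pattern recognition (PR).** Five time-domain features per channel on
  sliding windows of high-pass-filtered sEMG feed a small multilayer
  perceptron that decodes one of five motion classes; the decoded class
  selects a cursor direction and a proportional signal (the averaged,
  MVC-normalized voluntary envelope) scales it.

Either controller's 2-vector output is converted to an estimated force with
a 1 N gain and drives a first-order admittance (virtual mass–damper) model
whose output is the cursor velocity. The motivation is assistive control for
people with Duchenne muscular dystrophy (DMD), whose sEMG is much weaker and
less muscle-specific than healthy sEMG but remains decodable; the virtual
dynamics add a personalization layer (a less fatiguing virtual mass, a more
stabilizing damping) that plain proportional myocontrol lacks.

Because no public sEMG dataset accompanies the protocol, the package ships a
seeded synthetic sEMG generator and a virtual user, so whole sessions run
closed-loop with no human input. Everything downstream of the generator —
calibration, training, control, dynamics, statistics — is exactly the
processing a real-time system would run.

## Signal pipeline

Raw sEMG (6 forearm channels, 1 kHz) is processed causally, never
zero-phase, because the real system is online:

1. 2nd-order Butterworth high-pass, 20 Hz cutoff (movement artifacts, DC
   drift);
2. full-wave rectification;
3. 4th-order Butterworth low-pass, 2 Hz cutoff, producing the envelope.

Coefficients are designed at run time from the sampling rate (bilinear
transform via `signal::butter`), so non-1 kHz material works. All stages
carry filter state across chunks: streaming a signal through
`emg_stream_step()` in arbitrary chunk sizes reproduces the one-shot result
to machine precision, which is both the real-time contract and a test
invariant. The low-pass can ring slightly below zero after rectification;
envelopes are clamped at zero since they estimate an amplitude.

**Calibration.** The rest level of each channel is the mean envelope over
the last 3 s of a rest recording; the MVC level is the mean envelope over
the contiguous 3 s window of the MVC recording with the greatest summed
forearm envelope (robust to ramp-up — the protocol does not say which 3 s
to use). `calibrate()` rejects calibrations whose MVC/rest ratio falls
below 1.5 on any forearm channel: a genuine contraction sits far above
that, so a violation means the subject never contracted or the recordings
were swapped. Envelope arithmetic stays in millivolts; normalization to MVC
happens only inside the controllers.

## Direct control

With voluntary envelopes `E_vol = E_env − E_rest` (clamped at 0), the
normalized activations are `U_e = E_vol,e / E_mvc,e` and likewise `U_f`,
each clamped to [0, 1]; the control signal is `U = U_e − U_f ∈ [−1, 1]`.
A deadband (default 0.02 MVC) zeroes rest-noise drift. The mapping presets
follow the experiment's table: for right-handed use, wrist extension moves
the cursor right on the x axis and down on the y axis (flexion up); the
left-handed and DMD (supinated forearm) presets invert the convention.
Exactly one output component is ever nonzero — DC is sequential, 1-DOF at a
time.

**Mode switching.** The active axis toggles when both antagonists exceed
the co-contraction threshold (default 0.50 MVC), or, in the trigger
variant, when the normalized trigger-muscle envelope exceeds its threshold.
Two guards make the detector behave like a discrete command:

* a refractory period (default 0.5 s) between toggles, and
* edge triggering — after a toggle the detector re-arms only once the
  switch signal has fallen back below threshold, so one sustained
  co-contraction is one switch, however long it is held.

The 0.50 default deserves a note: when a user reverses direction (extensor
burst immediately after a flexor burst), the decaying and rising envelopes
cross at roughly 0.45 MVC, so thresholds much below 0.5 fire false switches
on ordinary reversals. The original protocol adjusted this threshold per
subject "to a comfortable level"; 0.50 is the analogous choice for the
virtual user. Control output is zeroed on ticks where the switch condition
holds, so switching never drags the cursor.

## Pattern recognition

Features per channel and 250 ms window (125 ms slide, i.e. class decisions
at 8 Hz): root mean square, mean absolute value, zero crossings, slope sign
changes, waveform length. ZC/SSC use an amplitude deadband (default
0.01 mV, the generator's noise-floor scale). Features are computed on
high-pass-filtered raw sEMG — the standard input stage for this feature
set. Training follows the protocol: five repetitions of 2 s per class,
five classes, giving 15 windows per repetition and 375 labeled vectors.

The classifier is a 30→10→5 MLP: z-scored inputs (training statistics;
without scaling, waveform length dwarfs the count features), one hidden
layer of ten logistic units, softmax readout, argmax class (first index on
ties). Training uses `nnet` with a fixed seed — identical seeds give
identical weights — and an iteration cap of 500; hitting the cap is
recorded in the model metadata as a convergence warning rather than an
error, matching how such models are used in practice. Prediction is an
explicit forward pass from the stored weights, so a JSON-serialized model
reproduces predictions exactly.

The proportional signal averages the six voluntary envelopes and normalizes
by the mean forearm MVC envelope, clamped to [0, 1]. The decoded class
routes it onto one signed axis; NO_MOTION forces (0, 0) regardless of the
proportional value. No majority-vote smoothing is applied to the class
stream; the class updates at the slide rate while the proportional signal
updates every control tick.

One generator choice matters here: the five training repetitions are
rendered at intensities 0.5–0.9 rather than a single fixed effort.
Repetitions of a "comfortable contraction" genuinely vary in effort, and
that variation is what makes the classifier robust across the intensity
range met online — trained at a single intensity, it mislabels weak
contractions as rest (we measured 53 % online accuracy at intensity 0.3 for
the high-crosstalk profile, versus 100 % with varied-effort training).

## Admittance cursor model

The cursor obeys `H(s) = v(s)/F(s) = 1/(A s + B)` per axis, force in from
the controller (1 N gain), velocity out. Presets carry the study's
personalized parameters: healthy `A = 6.6e-4, B = 4e-4`; DMD
`A = 5e-4, B = 6e-4` — the DMD user preferred a lower virtual mass (less
fatiguing) and higher damping (more stable). The behaviorally meaningful
quantity is the time constant `τ = A/B`: 1.65 s healthy, ≈0.833 s DMD.

Integration is the exact zero-order-hold solution of `A v̇ + B v = F`, not
Euler: `v⁺ = F/B + (v − F/B) e^(−dt/τ)` with the closed-form velocity
integral for position. Trajectories are therefore independent of the step
size between force updates (a test invariant), and the control tick
(default 10 ms) is purely a control-rate choice. Positions are clamped to
the [−1, 1]² workspace with the velocity zeroed on the clamped axis.

The raw parameters imply a terminal speed `1/B` of thousands of units per
second — the original workspace units are unstated — so `velocity_scale()`
multiplies A and B by a common gain, preserving τ exactly while setting the
full-effort terminal speed (default 2 workspace units/s). One consequence
worth knowing: reaching time is *not* monotone in B when A is held fixed,
because raising B also shortens τ and a shorter coasting tail helps the
user; varied with τ held (the `velocity_scale` semantics), higher damping
means a slower cursor and monotonically longer reaching times, which is the
form the damping sanity check takes.

## Synthetic sEMG generator

Each channel is amplitude-modulated band-limited noise: unit-variance
Gaussian noise band-passed to 20–450 Hz, multiplied by
`channel_gain × activation`, plus an independent noise floor (0.01 mV RMS).
A 6×5 synergy matrix maps each motion class to a channel activation
pattern (FCU-dominant flexion, ECU-dominant extension, mid-channel-dominant
hand open/close); crosstalk mixes in a fraction of the mean off-class
pattern. Commands pass through a 100 ms first-order lag emulating
electromechanical smoothing. The DMD profile has 0.35× the healthy channel
gains and crosstalk 0.5 versus 0.1 — qualitative, deliberately
conservative renderings of "considerably lower amplitude" and "fewer
independent activations"; they are free parameters, not estimates of any
individual. The DMD profile adds a seventh trigger channel (a remote
muscle) rendered the same way and driven only by discrete switch commands.

What the generator does *not* model: motor-unit dynamics, fatigue,
electrode shift, impedance drift, inter-day variation. Tests passing on
this generator show the *processing chain* is correct and the *simulated
conditions* behave as designed; they do not certify performance on real
recordings.

## Virtual user

The user closes the loop in place of a human. Every 125 ms it observes the
cursor and issues a command applied after a reaction delay (0.25 s):

* **Coast prediction.** Commands are based on the predicted stop point
  `p + v·τ` rather than the position — an experienced user internalizes
  first-order dynamics. The predicted stop integrates the command directly,
  which makes the policy a stable feedback loop on a pure integrator.
* **Proportional effort.** Commanded intensity ramps linearly with the
  predicted error over `ramp_dist` (default 1.2 workspace units), capped at
  `activation_level` (0.9). This gain must respect the ~0.5 s of loop delay
  (reaction + envelope lag + decision cadence); much higher gains
  limit-cycle. Because the approach time constant is `ramp_dist` divided by
  the controller's proportional gain times the terminal speed, the weaker
  PR signal (a six-channel average) yields a slower approach than DC — an
  emergent contrast, not a per-method parameter.
* **Method-specific floors.** Under PR the user never commands below 0.30
  intensity: weaker contractions would not be recognized by a classifier
  trained on firm ones, so fine corrections become brief firm pulses. DC
  has no classifier and can grade corrections down to 0.12.
* **DC switching.** A move/switch/settle state machine: finish the active
  axis (within `axis_tol` = 0.04), hold a co-contraction (or the trigger)
  until the mode actually toggles, then pause 0.5 s to re-orient before
  moving. Mode switching is deliberately not free; it is what makes DC
  expensive in 2-DOF tasks.
* **Decision errors.** With probability 0.15 per motion decision (a
  novice-level online error rate) the commanded class is replaced by a
  random wrong one for one decision interval. Under DC, errors landing on a
  hand class produce almost no antagonist imbalance, so DC absorbs most of
  them — another emergent asymmetry.

With these defaults the simulated study reproduces the qualitative regime
the protocol was designed to expose: DC is faster for 1-DOF reaching, PR
for 2-DOF, in both cohorts, with plausible magnitudes. This is a property
of the simulator configuration, asserted as a regression test; it is not a
claim about, or a fit to, any human's data.

## Task protocol and analysis

Eight circular targets: four on the axes (1-DOF condition), four on the
diagonals (2-DOF). The reference layout gives no coordinates, so defaults
put centers at component distance 0.55 with radius 0.08, all configurable.
Targets appear sequentially in numerical order, ten trials per target, the
first two per target discarded as practice; the DMD protocol uses the
reduced sets {1, 2} and {6, 8}. A trial succeeds when the cursor stays
inside the target for an uninterrupted 2 s dwell (the dwell clock resets on
any exit); the reaching time is the dwell start and excludes the dwell
itself. Trials time out at 30 s (the protocol had no timeout — humans
always finished; timeouts are excluded from reaching statistics and
reported as a failure rate). The cursor resets to the center between
trials; the DC mode state persists across trials within a session. The
simulated trials are i.i.d. given the seed — no learning is modeled — but
the discard bookkeeping is kept so event counts match the protocol: 32
analyzed events per condition for the healthy schedule, 16 for the DMD
schedule.

`summarize_trials()` reports mean and SD (sample SD by default; the
population divisor is an option) of reaching times over analyzed successful
trials, plus histograms with 1 s bins anchored at 0. For multi-subject
tables it first averages per target × trial index across subjects and then
pools, mirroring how multi-subject reaching data are usually reduced;
direct pooling is available via `subject_average = FALSE`.

## Problem sizes and determinism

Every stochastic step takes an explicit seed: recordings are bit-identical,
training is deterministic per seed, sessions derive per-trial seeds from
the session seed. The test suite and the acceptance script each simulate
one virtual subject per cohort with full 40- or 20-trial sessions per
condition; the method-ordering regression uses twenty reduced session
replicates (one trial per target) per condition. These sizes were chosen so
the complete suite runs in a few minutes on a laptop while leaving the
seed-averaged contrasts far clearer than their run-to-run variability.

## Known limitations

* The synthetic sEMG is a surrogate; none of the reported reaching-time
  magnitudes should be read as predictions of human performance. The human
  study's values serve only as plausibility envelopes.
* The virtual user is a control policy, not a cognitive model: no learning,
  no fatigue, no strategy changes within or across sessions.
* The DMD profile's amplitude ratio and crosstalk are free parameters with
  defaults chosen for qualitative contrast.
* Single-axis DC motion and five-class PR are the only control schemes;
  simultaneous multi-DOF control, regression-based proportional PR and
  alternative classifiers are out of scope.
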