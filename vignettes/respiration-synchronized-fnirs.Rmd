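---
title: "Respiration-synchronized fNIRS BCI: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration-synchronized fNIRS BCI: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`rsbci` implements a respiration-synchronized fNIRS motor-imagery (MI)
brain–computer interface and its companion personalization engine for
upper-limb rehabilitation. This vignette records the scientific models the
package encodes, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, and the design
decisions taken where the methodology left genuine freedom.

# The signal model

## Hemodynamics

Each channel's oxyhemoglobin change (ΔHbO, mol/L) is modeled as the sum of

1. a **task-evoked response**: the cue boxcar convolved with a canonical
   double-gamma hemodynamic response function (peak 6 s, undershoot 16 s,
   undershoot ratio 1/6). The convolved regressor is normalized to unit peak
   so that `hrf_amplitude` is the peak evoked ΔHbO in mol/L. Channels on the
   hemisphere contralateral to the imagined limb carry the full amplitude;
   ipsilateral channels carry `ipsi_gain` (default 0.3) of it; idle trials
   carry none;
2. a **respiration-coupled oscillation**: `resp_osc_amplitude · g_c ·
   sin(φ(t))`, where φ(t) is the instantaneous respiratory phase (0 at each
   inhalation onset) and `g_c ~ U(0.5, 1.5)` is a per-channel scalp-coupling
   gain. Coupling at the instantaneous breath phase — rather than at a fixed
   frequency — is what makes inhalation-locked cue timing effective and
   breathing irregularity disruptive;
3. **cardiac pulsation** (`pulse_amplitude` at `pulse_rate_hz`, default
   1.2 Hz ≈ 72 bpm), **linear drift** (`drift_slope` with a per-channel
   gain), and **white measurement noise** (`noise_sd` per sample).

ΔHbR is −1/3 of the evoked ΔHbO component plus attenuated confounds — enough
structure for the dual-wavelength inversion to be non-trivial, while the
analysis (deliberately) decodes HbO only.

Concentrations map to dual-wavelength intensity through the forward modified
Beer–Lambert model, `ΔOD(λ) = (ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR)·d·DPF` and
`I = I₀·10^(−ΔOD)` with `I₀ = 1` (absolute intensity is never interpreted).
Extinction coefficients at 760/850 nm come from the standard compiled
tabulation used by common fNIRS toolchains; `DPF = 6` and `d = 3 cm` are the
usual adult defaults. All of these live in `extinction_table()` and are
editable; the analysis inverts the same 2×2 system, so the forward–inverse
round trip is exact to numerical precision (a tested invariant).

## Respiration and its detection

Breathing is quasi-periodic: cycle periods are drawn per cycle from
`Normal(breath_period_s, period_jitter_sd)`, truncated below at half the mean
period. Defaults, 4 s ± 0.3 s (0.25 Hz), sit in the typical adult resting
band. The abdominal strain signal is `−cos(φ)` plus sensor noise: the trough
marks the start of abdominal expansion. **Convention:** "inhalation onset" is
the trough of the strain signal. The underlying measurement only promises
detection of expansion or contraction, so the package fixes the trough-onset
convention explicitly and timestamps every detected event at the trough.

`detect_inhalations()` is causal (streaming-compatible, a tested invariant):
an onset is emitted once the signal has risen above the running trough by
`hysteresis_frac` (default 0.3) of the running peak-to-trough amplitude, with
a refractory period of `min_breath_s` (default 1.5 s) between onsets. The
relative hysteresis adapts to slow amplitude changes; the refractory period
prevents double-triggering on noise. A flat trace yields zero events. When no
inhalation arrives within `timeout_s` (default 10 s) of the preparation end,
the scheduler flags and skips the trial rather than stalling — behavior the
protocol itself leaves unspecified.

## Protocols

The laboratory session is 4 blocks × 40 trials of balanced left/right
imagery (2 s preparation, 10 s cue, 10 s inter-trial interval; 160 trials).
The clinical calibration session is 4 runs × 80 trials, half MI and half
idle (320 trials); its cue/ITI of 6 s/4 s is chosen to land on the reported
≈12 s trial, and only the counts are load-bearing. In synchronized mode the
cue fires at the first inhalation at or after the preparation end and the
extra delay is logged as the per-trial wait; in conventional mode the cue
fires exactly at the preparation end. Cue intervals are half-open
`[onset, onset + cue_s)`; all times are seconds from session start.

# The dispersion index

With per-trial pre-cue HbO segment means `x_i` (the mean over the 2 s
baseline; the statistic is a design choice, since "HbO values" per segment
could also mean single samples or pooled samples — alternatives are reachable
by epoching differently), the dispersion index per channel is

```
DI = Σᵢ (xᵢᴮ² − x̄ᴮ²)² / Σᵢ (xᵢᴮ¹ − x̄ᴮ¹)²
```

averaged over channels for `DI_mean`. B2 are synchronized baselines, B1
conventional ones; DI < 1 means synchronization reduced baseline dispersion.
DI is invariant under joint affine rescaling of both segments (tested).

**How B1 is obtained matters.** For a participant recorded only under the
synchronized protocol, B1 must be emulated. Re-epoching the same recording at
time-shifted onsets randomizes respiratory phase but also slides the baseline
along the previous trial's undershoot, so those surrogate baselines absorb
task-evoked variance and bias DI downward even when there is no respiratory
oscillation at all. `run_pipeline()` therefore computes DI from a **paired
conventional-protocol twin**: a second simulated session of the same
participant, unsynchronized, with per-trial waits drawn `U(0, breath period)`
so both arms share the task structure and timing-jitter statistics and differ
*only* in respiratory-phase alignment. Under this pairing the index is
centered at 1 when the oscillation amplitude is zero and falls below 1 when
it is present — both ends are exercised by the acceptance suite. The
within-recording emulation remains available in `extract_epochs()`
(`b1_mode = "phase_jitter"` or `"uniform"`) and is documented as approximate.

# Decoding

Post-cue HbO (0–9 s; 9 s is the epoch extent appropriate to the slow
hemodynamic response) is averaged into `n_time_bins = 3` equal bins per
channel and vectorized: 20 channels × 3 bins = 60 features. Three bins keep
one feature per ~3 s — roughly the response's rise, plateau, and decay —
while keeping the covariance estimable from tens of trials; the granularity
is otherwise free. Features are z-scored **inside** each cross-validation
fold using training-fold statistics only; corrupting a held-out trial
provably changes no other trial's decision value (tested).

The classifier is a linear discriminant with shrinkage-regularized pooled
covariance, `S_γ = (1 − γ)S + γ·mean(diag(S))·I`, `γ = 0.3` by default:
with 60 features and ≈36 training trials per fold the sample covariance is
singular, so plain LDA is not estimable and shrinkage is the standard
remedy. Folds are stratified with a fixed seed. AUC-ROC is computed from the
pooled out-of-fold decision values (per-fold averaging is available behind a
flag); sensitivity and specificity treat the MI class as positive.
Above-chance testing is a one-tailed one-sample t-test of fold accuracies
against 0.5 at `α = 0.05 / n_participants` (0.005 for 10); zero-variance
fold accuracies fall back to an exact comparison, which is reported.

# Personalization

Movement scoring works on a common time base: every repetition is linearly
resampled to 101 points (0–100% of movement) before averaging — the shared
`t` that the scoring formulas presuppose but never define. The deviation
score DSS of a subject for one task and joint is the DTW cost (classic DP,
absolute-difference local cost, steps {(1,0), (0,1), (1,1)}, no window, raw
cost without path normalization — matching the bare `DTW(·,·)` notation;
normalization is an option) between the subject's repetition-mean trajectory
and the pooled mean of the age-matched normative subjects. For normative
subjects the reference excludes the subject itself (leave-one-out); for
patients it uses the full age-matched pool. DSS is computed **per joint**:
the screening rule speaks of "all joint movements", so per-joint normative
distributions feed both the interval screen and the z-scores (a sum over
joints inside DTW is the documented alternative). Age matching uses decade
bins.

The 95% normative interval is parametric, `mean ± 1.96·sd` of the pooled
normative DSS, with the lower bound clipped at 0 (DTW costs are
non-negative); a percentile variant would need far more normative subjects
than a desk-scale study carries. A task needs rehabilitation unless the
patient's DSS for **all** of its joints lies inside the interval. Flagged
tasks get `FS = Σ_joint W·z`, with ROM-ratio joint weights normalized within
task; since z measures deviation from normal, **higher FS = greater deviation
= higher priority**, flagged tasks are ranked by descending FS, and the top 4
map to activities of daily living through an editable YAML correspondence
table (the shipped pairing is synthetic, chosen by movement similarity).

Note a structural property of the screen: with 6 tasks × 4 joints tested
against 95% intervals, a healthy patient is occasionally flagged on a
marginal task by construction. Whether such false flags are rare therefore
depends on the *correlation* of a subject's deviations across joints — which
is why the kinematic generator gives each subject a shared offset and
amplitude gain (body geometry and movement habit travel with the subject)
plus a smaller independent per-task/joint component, rather than independent
idiosyncrasy per cell. Under that structure the acceptance suite verifies
that zero-impairment patients select no tasks in the majority of runs and
stay inside the intervals in ≥90% of screens, while impairment concentrated
on specific tasks puts exactly those tasks at the top of the ranking.

# What the generators emulate — and what they do not

Emulated: quasi-periodic breathing with period jitter; phase-locked HbO
oscillation with per-channel coupling; task-lateralized double-gamma
responses; cardiac pulsation, drift, white noise; strictly positive
intensities; normative kinematics with subject-level idiosyncrasy and
repetition noise; impairment as reduced range of motion, temporal phase
distortion, and offset shift.

Not emulated: motion artifacts (spikes, baseline shifts), superficial/scalp
hemodynamics that short-separation channels would regress out, heteroscedastic
or 1/f sensor noise, respiratory amplitude variation within a session,
learning or fatigue effects across blocks, EEG of any kind, and marker-based
inverse kinematics (joint angles are consumed as already extracted). Passing
tests therefore demonstrate correctness of the *pipeline* under the stated
generative model, not robustness to every artifact of real recordings.

# Study conditions and problem sizes

The package's studies run at these sizes, chosen as desk-scale versions of
the protocol that keep every statistical property measurable:

- Single-participant pipeline runs: 1 block × 40 trials, 20 channels.
- Dispersion study: 50 participants per arm (oscillation present/absent).
- Dispersion–accuracy cohorts: 50 cohorts × 10 participants; per-cycle
  breathing jitter spans 0.05–2.0 s across a cohort (metronome-regular to
  severely irregular) at fixed oscillation amplitude. In this cohort
  emulation the respiratory oscillation is set to twice the evoked amplitude
  with low white noise: systemic oscillations in raw fNIRS routinely match
  or exceed evoked responses, and a respiration-limited cohort is the
  population in which synchronization quality drives decoding — breathing
  *irregularity*, not oscillation size, is what varies between participants,
  because greater amplitude alone lowers both the dispersion index and
  accuracy together and cannot produce their observed anticorrelation.
- Permutation chance level: 200 trials × 60 features, 100 permutations.
- Personalization: 12 normative subjects × 3 repetitions × 6 tasks ×
  4 joints, 50 seeds per arm. Twelve normative subjects is the practical
  floor for the parametric interval: estimated from many fewer scores,
  `mean ± 1.96·sd` under-covers noticeably (t-distribution tails).

Defaults for single sessions keep the respiration oscillation at half the
evoked amplitude (the free amplitude ratio is otherwise unconstrained) with
`hrf_amplitude = 5e-7 mol/L`, matching the 10⁻⁷ mol/L display scale of
typical HbO epochs.

# Numerical choices

- Zero-phase filtering (forward–backward Butterworth) suits offline analysis
  of recorded sessions; a causal single-pass variant exists for online
  simulation. Inputs are demeaned and reflection-padded (three high-pass time
  constants) before `filtfilt`, otherwise initialization transients of the
  0.05 Hz edge leak far into the data.
- Optical density uses the channel-wavelength temporal mean as reference
  intensity, so recovered concentrations are unique up to an additive
  constant; per-trial baseline correction removes it.
- The 2×2 Beer–Lambert system is solved exactly; a singular extinction
  matrix is a configuration error.
- DTW runs in compiled code (`src/dtw.cpp`); tests verify it against
  exhaustive path enumeration for short sequences.
- Interval bounds use `qnorm(0.975)` (1.959964…), not the rounded 1.96.
- Boundary conventions are explicit: zero-variance fold accuracies fall back
  to exact comparison; a zero mean gain with zero variance reports p = 0.5;
  sensitivity/specificity on single-class labels are NA with a warning.
- Clinical outcome changes are computed against the week-0 pre-intervention
  score (the week-12 comparison in particular), and the improvement
  direction of the one-tailed test is "gain > 0".

# Known limitations

- The personalization z-scores are computed on DSS distributions, not on raw
  joint-angle means; the latter reading of the scoring formulas is noted but
  not implemented.
- The dispersion index is averaged over all channels; a single-channel or
  region-of-interest variant is a trivial restriction of the per-channel
  output but is not a separate code path.
- SNIRF (HDF5) import/export is not provided; sessions exchange as tidy CSV.
- The detector's trough timestamps inherit the respiration sensor's sampling
  grid (default 25 Hz); sub-sample interpolation is not attempted.
- Clinical outcome analyses operate on supplied score tables; the package
  does not attempt to reproduce any particular trial's patient values, which
  depend on recordings that are not distributable.
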