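---
title: "explorekit: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{explorekit: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(explorekit)
```

This vignette is the package's own account of the analysis methods it
implements: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generators emulate (and
what they deliberately do not), and the numerical and design choices made
where the methods left room. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Photometry processing

### Model

A two-channel fiber-photometry recording consists of a calcium-dependent
465 nm signal and a calcium-independent (isosbestic) 405 nm reference.
The signal channel is modeled as

  bleaching trend + slow background fluctuation + calcium transients +
  shared motion artifacts + measurement noise,

and the reference channel as the same minus the transients (calcium
invisible at the isosbestic wavelength), with its own bleaching constant
and a channel-specific artifact gain. The processing chain exploits this
structure step by step, in a fixed order that is recorded as provenance in
every `processed_trace`:

1. `decimate_raw` — block averaging by an integer factor (the block mean
   doubles as the anti-alias smoother). Optional; acquisition systems
   often do this on the fly.
2. `resample_uniform` — linear interpolation onto a uniform grid
   (default 100 Hz). All later windowed operations assume this grid.
3. `interpolate_artifacts` — user-flagged regions (cable tugs, etc.) are
   replaced by the line joining the boundary samples.
4. `lowpass` — zero-phase 4th-order Butterworth, default cutoff 2 Hz.
   Only the cutoff is contractual; tests assert response properties
   (≥ 95% amplitude at 0.1 Hz, ≤ 10% at 20 Hz) rather than
   coefficients. The implementation reflect-pads around the edge values
   before `signal::filtfilt`, because unpadded filtering of a trace with
   a large offset (the bleaching baseline) produces edge transients
   large enough to corrupt the windowed statistics downstream.
5. `bleach_correct` — least-squares fit of `a·exp(−t/τ) + c`, subtracted.
   The offset `c` matters: photodetectors sit on a nonzero baseline. A
   near-constant trace is treated as the degenerate case (subtract the
   mean) rather than an error. A double-exponential is deliberately not
   the default; with 10-minute sessions a single exponential plus offset
   is identifiable and stable.
6. `motion_correct` — the reference is regressed onto the signal
   (polynomial fit, default degree 1) and the fitted component is
   subtracted. Degree 1 is an ordinary linear regression; higher degrees
   are available via `motion_poly_degree` for nonlinear channel gains.
   A flat reference is an error, not a silent no-op.
7. `rolling_zscore` — `z = (f − f0) / f1` with `f0`, `f1` the mean and
   standard deviation in a centered 60-s moving window, truncated at the
   edges. Centered-vs-trailing is a genuine choice; centered is used
   because it makes the normalization symmetric around behavioral events
   and keeps the z trace free of systematic lag. Windows with zero
   variance are a contract error. The implementation is O(n) via prefix
   sums; the test suite holds it to 1e-10 agreement with a direct
   O(n·w) computation.

Bleach correction precedes motion correction, matching the order in which
the corrections are usually described; since each channel is detrended
separately before the regression, swapping the two steps changes results
only marginally (the regression would absorb a shared trend).

### Event-triggered statistics

`epoch_auc` is the mean z over a half-open epoch — a time-normalized area
under the curve, so epochs of different lengths are comparable.
`event_triggered` aligns ±5-s snippets at behavior initiations, averages
them, then computes a baseline (mean over lags −5 to −3 s of the averaged
trace) and a corrected extremum (max or min over lags 0 to 3 s, minus the
baseline). The polarity is caller-selected because activation analyses
(rearing, head-dips) use the maximum while suppression analyses
(thigmotactic locomotion) use the minimum. Onsets closer than 5 s to a
trace edge are dropped with a warning; dropping all of them is an error.

### Why the baseline window ends 3 s before the event

Calcium indicators are slow (the generator's kernel decays with
τ ≈ 1.5 s); activity around initiation bleeds backwards through the
smoothing and the moving-window mean. Ending the baseline window at −3 s
keeps it clear of this bleed while staying inside the snippet.

## 2. The synthetic photometry generator

`gen_photometry` emulates a 10-minute session at 100 Hz: exponential
bleaching (default τ = 300 s, distinct constant for the reference), a
band-limited unit-sd background (white noise smoothed with a 0.25-s
Gaussian kernel, so the 2-Hz filter passes it almost untouched), 20
event-locked transients, 15 shared artifacts (Gaussian bumps, sd 0.15 s,
amplitude 8 background-sd units, gain 0.8 in the reference), and white
measurement noise (sd 0.5). Events are spaced at least 12 s apart and
artifacts at least 6 s from any event, so each effect is separately
measurable. The transient kernel is a double exponential with 0.2-s rise
and 1.5-s decay, normalized to unit peak — a GCaMP6s-like shape whose peak
falls ~0.5 s after onset, well inside the 0–3 s extremum window.

**Amplitude semantics.** Ground-truth transient amplitude is expressed in
the z units of the moving-window normalization. Because the planted
transients themselves contribute variance to the 60-s window, a transient
planted at k background-sd units is measured below k after normalization.
The generator therefore solves `s / sqrt(bg² + s²·v) = A` for the raw
peak scale `s`, where `v` is the windowed variance of the unit-amplitude
transient field at the event peaks — a quantity the generator knows
exactly from its own schedule. This makes "amplitude 2.0 z" mean exactly
what the pipeline's own unit means, and makes parameter recovery a test
of the processing chain rather than of unit bookkeeping.

**Artifact-power measurement.** Suppression by `motion_correct` is
quantified as excess power: mean z² in ±0.5 s around artifact times minus
the quiet-period mean z², compared between pipelines with and without the
motion step. Raw z² at artifact times contains ~1 z² of background power
in either pipeline and would understate the suppression of the artifact
itself.

**What the generator does not emulate:** hemodynamic contamination,
wavelength-dependent bleaching interacting with motion, lock-in
demodulation residues, or nonstationary noise. Passing recovery tests on
generated sessions therefore demonstrates correctness of the processing
chain under its model assumptions, not robustness to every failure mode
of real recordings.

## 3. Behavioral classification

Speed is computed from Gaussian-smoothed positions (1-s window; kernel sd
= window/4, renormalized at the edges) times the frame rate; a zero
window degenerates to the raw finite difference. All detectors compare
against this one smoothed speed series.

The numeric rules, all overridable through the config `thresholds` block:

| rule | default | comparison |
|---|---|---|
| immobility speed | 6 cm/s | strict `<` |
| immobility motion | 1 % | strict `<` |
| immobility run length | 15 frames | strict `>` |
| locomotion speed | 6 cm/s | strict `>` |
| locomotion bout distance | 10 cm | `>=` |
| pause speed | 3 cm/s | strict `<` |
| pause duration | 1 s | `>=` |
| focused-exploration gap | 5 s | `<=` |
| thigmotactic zone | 25 % of extent | linear, per side |
| puncta positivity | 4 puncta | `>=` |

Strictness follows the wording of each rule ("over 15 frames", "greater
than 60 mm/s", "less than 6 cm/s"); a frame at exactly 6 cm/s is neither
immobile nor locomoting and falls to surveying, the residual category.
Intervals are half-open `[start, stop)` everywhere, which makes zone
times partition the session exactly and prevents double counting at
epoch boundaries.

Open interpretation points, decided as follows:

- **"Periphery (25%)"** is read linearly: the outer band occupies 25% of
  each side's extent (12.5% of the side at each wall), the convention of
  common tracking software. An area reading (band covering 25% of the
  arena area) is available as `zone_mode = "area"`.
- **Focused-exploration chaining** applies the 5-s rule to successive
  end-to-start gaps, merged transitively; an episode runs from the first
  dip's start to the last dip's end, needs ≥ 2 dips, and every dip ends
  up in exactly one category (episode member or isolated). A gap of
  exactly 5 s chains ("within 5 s").
- **Pre-normalization** is subtraction (metric − Pre), which remains
  defined when the Pre value is zero (common for head-dip counts); a
  ratio mode exists for users who want fold changes.
- **Ethogram precedence** is manual labels (grooming, rearing) over
  immobility over locomotion over surveying, because grooming and
  rearing are scored by an observer and can co-occur with low speed.

`gen_tracking` realizes scripted bouts as continuous paths: fast bouts
follow a wall circuit (3 cm inside the walls — thigmotactic) or a central
circle, with an explicit transit to the circuit at the bout's own speed;
slow and stationary bouts stay where they are (slow bouts orbit a small
local circle). Continuity matters: a position jump of a few centimeters
in one frame reads as a spurious high-speed locomotion bout. The default
script uses bout durations of 10–30 s so that the ~0.2–0.4 s of boundary
smear introduced by the mandated 1-s velocity smoothing stays below the
5% per-bout Jaccard budget used in validation; the 1-s and 15-frame
boundary rules themselves are tested separately with exact constructed
speed series. Per-frame motion percentages are scripted directly (0.2%
for immobility, 3% for stationary-but-active states, 5% for movement)
since they come from the tracker, not from kinematics.

## 4. Optogenetic unit classification

The protocol emulated by `gen_spiketrains` and consumed by the analysis:
1-min tonic baseline, six single 10-ms pulses at 5-s intervals, six
bursts (5 pulses, 10 Hz, 10 ms) at 5-s intervals. Baseline rates span
2.2–31.8 Hz, the tonic range of midbrain units. Responders are thinned
(exact for a rate that only decreases) by `inhibition_depth` in a window
opening `inhibition_latency` (default 20 ms) after each pulse.

Analysis decisions:

- **PSTH**: 100-ms bins, rates z-scored against the pooled pre-stimulus
  bins of the same unit, then averaged across trials. A unit silent in
  its entire pre-stimulus period has no z scale and is a contract error.
- **Stability rule**: a unit is discarded when its per-trial pre-stimulus
  rate varies more than 5× across trials (max/min). A mix of zero and
  nonzero pre-trial rates counts as an unbounded change and is
  discarded; a uniformly silent pre-period shows no rate *change* and is
  kept (it then classifies as nonresponsive unless stimulation evokes
  firing).
- **Response window**: burst onset to last-pulse offset plus 100 ms
  (0.51 s for the default burst). The extra 100 ms covers the
  short-latency tail; the window is configurable since it is a design
  choice, not a printed constant.
- **Per-trial baseline**: the 1 s preceding each trial, so slow drifts
  between trials cancel within each trial's own change score.
- **Statistics**: one-sample t-test of the six per-trial changes against
  zero; Benjamini–Hochberg across units at q = 0.05; the sign of the
  mean change separates inhibited from excited. Six changes with zero
  variance would leave the t statistic undefined; the documented rule is
  p = 0 when the common value is nonzero (a perfectly reproducible
  change) and p = 1 when it is zero (no evidence), which keeps batch
  runs alive without fabricating significance.
- **Latency**: the first post-stimulus bin whose trial-averaged z falls
  below −1.96/√(n_trials) — the criterion is on the mean of n
  unit-variance bins, which is what the averaged PSTH displays.

A statistical note computed by the validation runs: with 7 strong
responders among 27 units, BH at q = 0.05 admits a small expected number
of false discoveries among the 20 nulls (measured: at least one spurious
"excited" flag in roughly 8% of simulated experiments). The validation
therefore asserts the median counts across 100 simulated experiments
(7 inhibited, 0 excited) and that at least 6 of the 7 planted responders
are recovered in every experiment; demanding literally zero excited flags
across all experiments would contradict the method's own error model.

## 5. Puncta colocalization

Cells are positive for a channel when they carry ≥ 4 puncta (thresholds
independent per channel, configurable). Colocalization is reported as the
two conditional fractions — SYP⁺ cells that are vGLUT2⁺, and vGLUT2⁺
cells that are SYP⁺ — with set semantics (a double-positive cell counts
in both denominators). An empty denominator returns an explicit
`undefined_fraction` sentinel carrying a reason string, never a division
error: sparse sections with no positive cells are normal.
`count_validation` computes per-image overcount (automated − manual) and
percentage overcount, with means and standard deviations, for validating
an automated counting pipeline against manual counts.

`gen_puncta` draws SYP positivity as Bernoulli(p_syp), vGLUT2 positivity
conditionally on it, and gives positive cells 4 + Poisson(4) puncta and
negative cells 0–3; recovery is validated against exact binomial
confidence intervals of the generating probability.

## 6. Reproducibility machinery

Every generator requires an explicit seed and is bit-reproducible given
(config, seed). The CLI (`ek_run()` / `exec/explorekit`) writes a JSON
manifest per run — command, seed, config hash, package version, and MD5
of every input and output — so a processing chain can be verified
end-to-end: the outputs of `simulate` appear by hash among the inputs of
the stage that consumed them. Numeric tables are written with 17
significant digits so a write–read round trip restores doubles exactly.

## 7. Problem sizes used in validation

The validation studies run at: 20 photometry sessions of 10 min at
100 Hz; 3 scripted trajectories of ~3.5 min at 30 Hz plus exact boundary
series; 1000 random head-dip schedules of up to 10 dips against full
enumeration; 1000 null spike-train units and 100 replicates of the
27-unit/7-responder design; 1000 random puncta tables against brute-force
counting plus 200 recovery replicates. These sizes put Monte-Carlo error
well below the assertion tolerances while keeping the full suite under a
minute of compute.

## 8. Known limitations

- The photometry model assumes a single fiber and mono-exponential
  bleaching; biexponential bleaching in long sessions would leave a slow
  residual that the 60-s window partly absorbs but does not remove.
- Behavioral classification consumes tracker output (position, motion
  percentage); it does not detect grooming or rearing from video — those
  arrive as manual annotations and take precedence in the ethogram.
- The unit-response analysis starts from sorted spike times; sorting
  quality, drift and waveform issues are upstream concerns.
- Group-level inference across animals (Friedman, Dunn's, mixed models)
  is intentionally left to standard statistical functions on the
  per-session outputs that `report` aggregates; the package computes
  per-session quantities only.
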