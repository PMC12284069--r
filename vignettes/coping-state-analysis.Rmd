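---
title: "Segmenting coping states and quantifying habenular astrocyte calcium"
author: "copingtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting coping states and quantifying habenular astrocyte calcium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copingtrace)
```

## The problem this package addresses

When a mouse or a juvenile zebrafish faces an inescapable challenge (head
fixation, restraint, aversive stimuli), its behavior alternates between
bouts of vigorous struggling — *active coping* (AC) — and quiescent periods
— *passive coping* (PC). Astrocytes of the habenula show calcium elevations
locked to AC bouts, and disrupting their calcium signaling shifts the AC/PC
balance. Quantifying this requires a chain of small, exacting analyses:
segmenting a motion trace into an alternating AC/PC partition, correcting
fiber-photometry signals for motion artifacts, aligning and standardizing
calcium transients to bout onsets, mapping responsive regions in two-photon
movies, and applying a set of decision-rule statistics and inclusion
filters. `copingtrace` implements that chain as tested, reusable functions,
together with seeded synthetic generators so every stage can be validated
against a known ground truth without any recorded data.

## Bout segmentation

The segmentation contract is amplitude-plus-duration thresholding applied
once, in a fixed order, to a low-pass-filtered trace:

1. **binarize** — a sample is an active candidate iff its value is at or
   above the amplitude threshold (a tie counts as active);
2. **merge** — any sub-threshold gap shorter than the minimum PC duration
   that is flanked by supra-threshold runs is absorbed into the surrounding
   active region (a PC bout shorter than the minimum cannot exist between
   two AC bouts — this is what "minimum PC duration" means);
3. **prune** — any remaining active run shorter than the minimum AC
   duration becomes passive;
4. **emit** the alternating partition, tiling the session exactly.

Merge-before-prune is fixed as canonical (and mirrored by an independent
brute-force reference in the test suite): pruning first would let a short
gap split a long bout into two prunable halves, contradicting the
minimum-PC semantics. Intervals are half-open in seconds; sample *i* covers
`[t0 + i/rate, t0 + (i+1)/rate)`. Bouts touching the session edge are kept
if they meet the minimum duration within the recorded span, and the first
and last PC bouts may be shorter than the PC minimum (session truncation).

Default thresholds are the protocol values: spontaneous AC — 0.5 a.u.
motion index, 2 s minimum AC, 0.5 s minimum PC; evoked AC — minimum AC
raised to 2.7 s, filtering out the initial startle; open-field velocity
events — 6 cm/s, 1 s minimum duration, and at least 2 s of continuously low
velocity beforehand (an event too close to the recording start to verify
that quiet period is rejected). Stimulus-evoked response probability counts
a stimulus as responded only when a *new* AC onset falls within the latency
window (default 2 s, configurable — the protocol does not state one); an
ongoing bout does not count.

## Filtering and resampling choices

The motion trace is low-pass filtered (Butterworth, design order 1, 0.5 Hz
for motion index, 0.3 Hz for velocity) before thresholding. The filter is
applied **zero-phase** (forward–backward) by default: a causal filter
delays every edge by roughly its time constant (~0.3 s at 0.5 Hz), which
would bias bout onsets — and therefore every onset-aligned photometry
quantity — late. The cost is that the effective attenuation is that of a
filter of twice the design order; `order` always refers to the one-way
design, and a causal mode is available behind a flag. Because the shipped
`signal::filtfilt` handles edges poorly, the implementation demeans the
trace and pads it by odd reflection over several filter settle times before
filtering, so a constant trace passes through exactly (DC gain 1). Traces
shorter than three times the filter's 99% impulse-response width are
rejected rather than silently padded.

Photometry traces are smoothed with a causal exponential filter (time
constant 0.1 s), discretized exactly so the step response reaches
`1 − e⁻¹` at one time constant.

Sessions recorded at 16.67 Hz are brought to the common 10 Hz grid by
Fourier-domain (band-limited) resampling — spectrum truncation, not linear
interpolation — preserving every component below the output Nyquist
frequency. Fourier methods assume periodicity, so roughly the first and
last second of a resampled trace are edge-unreliable and should be excluded
from event detection.

## Photometry model

**Isosbestic correction.** Motion artifacts appear in both the
calcium-dependent channel (465/473 nm GCaMP, 570 nm jRGECO1a) and the
calcium-independent 405 nm isosbestic channel. The corrected signal is
`(signal − iso_fit) / iso_fit`, where `iso_fit` is the isosbestic trace
least-squares affine-scaled onto the signal channel. Subtracting the *raw*
isosbestic trace is not unit-safe — the two channels have different gains
and offsets — so the affine fit is the canonical mode, which also makes the
output invariant to affine rescaling of the isosbestic channel; a `raw`
mode is available. The fit absorbs the transients' nonzero mean, so the
corrected trace can differ from the "true" dF/F by a small gain/offset;
every downstream quantity is invariant to that (z-scoring) or estimated by
regression.

**Peri-event z-scoring.** Each trial is standardized by the mean and
*population* SD (the spec of a divisor is a reporting choice; population SD
is fixed and documented) of a pre-event baseline window: 3 s before a
stimulus, 5 s before a spontaneous AC onset. A PC bout is z-scored against
the baseline of the AC bout that precedes it — one shared baseline per
AC→PC transition, so both states of a transition are standardized on the
same footing. Trials whose baseline leaves the recording are dropped and
logged; windows running past the end are NA-padded. Per-animal
normalization divides all of an animal's trials by that animal's maximum
z-score within the dataset (the within-dataset scope is a documented choice;
the protocol does not state whether maxima are per session).

**Rise time.** The calcium rise time of a trial is the time from bout onset
to the trial's maximum z within the bout (plus an optional post-offset
margin); a trial whose peak never rises above the baseline level (z = 0) is
flagged unreliable. A 10–90% rise-time variant exists but is off by
default, since the protocol never defines "rising time" more precisely.
Rise times are regressed on bout durations by ordinary least squares, with
R² the squared Pearson correlation.

**Onset latency** between two signals aligned to the same events (e.g.
neuronal jRGECO vs astrocytic GCaMP) uses a z-crossing of 2.0 sustained for
0.2 s (both configurable; the protocol states no numbers) and a paired
signed-rank test on the per-event differences. **Calcium–kinematic
correlograms** mean-bin both traces at 1 Hz and report Pearson correlations
at integer-bin lags, with positive lag meaning calcium follows movement.

## Zebrafish two-photon analysis

Swim bouts are maximal runs where |tail angle| exceeds 0.65 rad, kept when
strictly longer than 1 s (both thresholds exclusive, following "above").
Registered movies are masked by thresholding the temporal-mean image with
Otsu's method (deterministic and parameter-free; a manual override exists),
then divided into 10×10-pixel bins. Each bin's trace becomes
`ΔF/F = (F − F0)/F0` with `F0` the bin's 10th percentile over the whole
recording — robust to transients, deterministic, and making ΔF/F invariant
to global gain; a mean-of-pre-bout baseline option is provided. Baseline
(5 s pre-onset) and response (10 s post-onset) window means are paired per
bout and compared by a one-tailed (response > baseline) Wilcoxon signed-rank
test; a bin is *responsive* iff p < 0.05. No multiple-comparison correction
is applied, deliberately: the test selects bins for downstream averaging,
it is not inference on individual bins. Windows leaving the recording drop
the bout; response windows are truncated at the next bout onset. Fewer than
five usable bouts is an error — the exact signed-rank distribution cannot
reach p < 0.05 below n = 5. Whether "average activity" means raw F or ΔF/F
is unstated in the protocol; ΔF/F is used. Responsive-bin testing is per
plane. Registration is assumed done upstream; a frame-to-mean-image
correlation QC score flags recordings with residual motion.

## Decision-rule statistics

Shapiro–Wilk is applied to every group at α = 0.05; parametric tests are
chosen only when **all** groups pass. Two groups route to the two-tailed
Student's t-test (pooled variance when unpaired — the protocol's reported
t(12) with n = 7 + 7 implies pooled df) or its nonparametric counterpart
(Wilcoxon signed-rank paired, Mann–Whitney U unpaired); more than two
groups route to one-way (repeated-measures when paired) ANOVA or
Kruskal–Wallis.

The signed-rank test uses **Pratt** zero handling (zeros ranked, then
dropped from the signed sums) with the exact null distribution for up to 25
zero/tie-free differences and a tie-corrected normal approximation with
continuity correction otherwise. This single fixed convention makes every
p-value in the pipeline reproducible on data with ties.

For the chemogenetic (DREADD) experiment, per-animal changes between
consecutive alternating saline/CNO sessions are computed, the saline→CNO
changes are sign-inverted (so both transition types share the expected
direction under a real drug effect), and the inverted changes are compared
across transition types by one-way repeated-measures ANOVA with animal as
the repeated factor. Note a structural subtlety: in a steady-state
alternating design, any purely session-label-determined effect produces
exactly opposite deltas for the two transition types, which the inversion
maps onto *equal* values — no type effect. The transition-type contrast is
therefore sensitive to departures from that symmetry, such as incomplete
washout; the synthetic scenario (below) is designed accordingly.

**Rabies tracing filters.** A brain region is included when more than 3
animals (≥ 4) each show more than 5 rabies-positive cells on 2 adjacent
sections; "more than" and "exceeding" are read as strict inequalities
throughout. The canonical reading sums counts over an adjacent section
pair; the stricter per-section reading (each section individually above
threshold) is available behind a flag, since the sentence admits both.
Animals are excluded when starter-virus spread outside the LHb exceeds 30%
or the neuronal fraction of starter cells exceeds 0.5% (strict); missing
metadata flags the animal for review instead of silently including it.
Neuronal fractions (RV⁺NeuN⁺ / RV⁺) are pooled per region across included
animals.

## The synthetic generators: what they emulate, and what they do not

All generators derive per-component child seeds deterministically from one
root seed and restore the caller's RNG state, so outputs are bit-exact for
a fixed configuration and composable across modules.

* **Motion sessions** — six-minute head-fixed sessions at 10 Hz. AC bouts
  are square supra-threshold pulses (amplitude 1.0 a.u., per-bout jitter SD
  0.1) on a zero-mean noise floor (SD 0.2, i.e. SNR 5); bout durations are
  log-normal (median 3 s, σ = 0.6), matching the right-skewed duration
  histograms of head-fixed mice qualitatively — not a claim about the real
  data — and floored at 2.5 s so that programmed bouts are recoverable under
  the 2 s minimum-duration rule. Edges are snapped to the sample grid so
  ground truth is exact in samples. Passive gaps are log-normal (median
  20 s), giving roughly 10–14 bouts per session.
* **Photometry sessions** — 20 Hz two-channel fluorescence. Each AC bout
  contributes a transient with time-to-peak `0.8 × duration + N(0, 0.3²) s`
  (truncated to `[0.2 s, duration + 1 s]`) and 2 s exponential decay; peak
  amplitude grows with bout duration (0.025 ΔF/F per second of bout), since
  both rise and amplitude track AC length in the system being emulated. A
  shared low-frequency artifact (low-passed noise, SD 2 a.u.) enters both
  channels; the 405 nm channel carries no transient.
* **Two-photon movies** — a 12-minute recording at 2.33 Hz (the per-plane
  protocol rate) with a bright astroglial rectangle (150 vs 20 a.u.
  background, Otsu-separable), a compact subset of 10×10 bins carrying
  bout-locked transients (0.3 ΔF/F), photon-like noise (SD ∝ √intensity),
  and a 120 Hz tail trace holding supra-threshold plateaus at exactly the
  programmed bout times. Swim bouts arrive at ~1.5/min (≈ 18 per
  recording); at that pair count the exact signed-rank test's attainable
  size (0.0494) is close to the nominal 0.05, so type-I calibration checks
  are meaningful.
* **DREADD scenario** — 8 animals × 6 alternating sessions; total AC time
  is an animal intercept (mean 150 s, SD 20) plus session noise (SD 7 s,
  consistent with the stability of spontaneous coping across sessions),
  with CNO suppressing AC by 60 s and the following saline session
  retaining half the suppression (incomplete washout). The carryover is
  what gives the two transition types different magnitudes — the scenario's
  "true effect" under the inversion RM-ANOVA; with full washout the design
  is exactly null by the symmetry noted above.

What the generators do **not** emulate: biophysical indicator kinetics
beyond rise/decay phenomenology, hemodynamic contamination, slow
photobleaching, oscillatory tail kinematics within a swim bout (the tail
trace is an envelope), inter-bout behavioral correlations, and z-drift in
movies. Passing the recovery tests therefore shows the pipeline is correct
under the stated signal model, not that it is robust to every artifact of
real recordings.

## Numerical choices and degenerate inputs

* Threshold ties count as active (`≥`); tail-angle and rabies thresholds
  are strict (`>`), following each rule's wording.
* Duration comparisons use a 1 ns tolerance so grid-aligned durations are
  not lost to floating-point rounding.
* A zero-variance baseline window is an error (z-scores undefined), as are
  empty pixel masks, constant images under Otsu, zero/negative fitted
  isosbestic values, and a per-animal maximum z ≤ 0 under normalization.
* Identical paired groups give a t statistic pinned to 0 with p = 1 rather
  than 0/0; an all-equal delta table gives F = 0.
* File ingestion interpolates NA gaps up to 0.5 s linearly (logged) and
  rejects longer runs.

## Problem sizes used by the test suite

The suite validates oracle equivalence on 1000 random traces, bout recovery
on 30 sessions, rise-slope CI coverage on 100 single-session runs,
responsive-bin type-I calibration on 20 null movies of 200 bins each
(4000 bin-tests), and spatial recovery on 10 movies at default effect size —
sizes chosen to make the binomial checks well-powered while keeping the
whole suite fast on one CPU. The same computations, re-seeded from the
command line, are what `scripts/acceptance.R` reports.

## Known limitations

* The evoked-response latency window and the onset-latency crossing
  parameters are configurable defaults, not protocol values.
* The group comparison of head-fixed cohorts reproduces the *procedure*
  used on the deposited animal recordings; reproducing the printed t
  statistics requires those recordings, which are not distributed with the
  package.
* Per-plane two-photon analysis does not stitch volumes across planes.
* The bout detector assumes a uniformly sampled, gap-free trace after
  ingestion; it does not model tracking dropouts longer than the NA-repair
  limit.
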