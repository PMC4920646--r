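---
title: "Detecting and quantifying spike-and-wave discharges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying spike-and-wave discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rat models of absence epilepsy such as GAERS (Genetic Absence Epilepsy Rat
from Strasbourg) express hundreds of spontaneous spike-and-wave discharges
(SWDs) per day: rhythmic ~5–12 Hz EEG trains, each cycle a sharp
high-amplitude spike followed by a slow wave, accompanied by behavioral
arrest. Pharmacological studies in these models quantify a drug's effect on
three seizure parameters — total time spent in seizures, number of
seizures, and mean duration of individual seizures — in 20-min epochs
around an injection at t = 0, after a 40-min control period, and typically
follow interictal (between-seizure) spectral power as a secondary readout
of vigilance.

`swdquant` implements that full analysis chain as reusable, tested code:

1. a **semi-automatic SWD detector** (amplitude-threshold crossings,
   grouping, amalgamation, duration filter, instantaneous-frequency
   criterion);
2. **ictal wavelet analysis**: Morlet continuous wavelet transform and
   ridge extraction of the per-SWD peak frequency;
3. **interictal band power**: anti-aliased resampling to 200 Hz, masking of
   seizures/artifacts/sleep, Gaussian-window short-time Fourier transform,
   five conventional bands with 48–52 Hz excluded from gamma;
4. **quantification and statistics**: per-epoch metrics, two-step
   normalization (control period, then vehicle group), overall effects,
   two-way ANOVA with Dunnett and Sidak post-hoc contrasts, unpaired
   t-tests on peak frequency;
5. a **synthetic session generator** with ground-truth annotations and
   parametric drug-effect models, so that every stage above can be
   validated end to end without animal data.

## The detector

Detection operates on one channel after DC removal (exponential
running-mean subtraction, time constant 0.1 s, i.e. a ~1.6 Hz first-order
high-pass). A reference segment of awake, desynchronized, artifact-free
control EEG defines baseline mean and SD; in the original workflow this
segment is chosen by the analyst, here `auto_baseline()` reproduces that
choice deterministically (longest clean control gap, capped at 120 s).
Threshold crossings above *mean + k·SD* and below *mean − k·SD*
(k ∈ [5, 9], default 6) are reduced to one event per excursion and
collapsed over a 60 ms window so a single spike-wave complex contributes
one peak. Peaks are grouped by four parameters: a putative SWD opens when
two peaks fall within the 0.2 s maximum onset interval, continues while
gaps stay below the 0.4 s maximum continuation interval, putative events
less than 0.5 s apart are amalgamated (iterated to a fixed point), and
events shorter than 1 s are discarded. Finally the instantaneous
frequencies `1/Δt` between consecutive peaks must lie within 5–12 Hz
(inclusive) for at least 75% of intervals; this is what rejects sleep
spindles (~10–14 Hz, but with sub-threshold amplitude in practice) and
broadband artifacts.

Conventions the source protocol leaves open, fixed here and regression-
tested: the duration boundary is inclusive (exactly 1.0 s survives); the
frequency band is inclusive at both edges; event extent is the first-to-
last peak extended by half the collapse window per side; the stage order
grouping → amalgamation → duration filter → frequency criterion is locked
by a test that shows permuting amalgamation and the duration filter changes
the result.

## Ictal and interictal spectral analysis

The per-SWD peak frequency is the time-average of the wavelet ridge: an
analytic Morlet transform with resolution parameter f0 = 1 (Gaussian
envelope with time SD `f0/f`, i.e. spectral SD `f/(2π f0)`), evaluated on a
linear 0.1 Hz grid over 5–14 Hz, amplitude-normalized so a pure tone has
the same ridge power at every analysis frequency. The ridge takes the
power argmax per time point, ties broken toward the lower frequency.
Edges are mitigated by 2 s reflection padding. Only treatment-period SWDs
(start ≥ 0) enter the per-animal average, which is the unweighted mean of
per-SWD means with SEM across SWDs; an animal without eligible SWDs is
missing, never zero. The ridge is averaged over the full event span: the
alternative of averaging only high-power time points is not implemented.

Interictal analysis resamples to 200 Hz through a zero-phase FIR low-pass
at 0.8× the target Nyquist (for 2-3-5-smooth lengths the filter response
is applied in the frequency domain together with exact bandlimited rate
conversion; otherwise a polyphase resampler is used). Samples belonging to
detected SWDs, annotated artifacts and sleep are excluded. The "f0 = 1"
short-time Fourier window is read as a Gaussian taper with ~1 Hz spectral
resolution: spectral SD 1 Hz, time SD 1/(2π) s, truncated at ±4 SD, hop of
half a window, evaluated at integer bins 1–80 Hz. Band power is the mean
one-sided spectral density over the band's integer bins — delta 1–4,
theta 5–8, alpha 9–12, beta 13–30, gamma 31–80 with bins 48–52 excluded
(mains) — computed per 20-min epoch on unmasked runs of at least 2 s,
averaged with run-length weights. Epochs under 10% unmasked are missing.
The 2 s run floor, the 10% epoch floor and duration-weighted averaging are
our choices (unstated in the source protocol); arithmetic means of absolute
power are used throughout. In the cohort pipeline excluded intervals are
padded by a 0.5 s guard band: detected event edges systematically
underestimate the true extent by ~0.2 s, and unmasked spike tails would
otherwise leak broadband power into the interictal spectrum.

## Quantification, normalization, statistics

Per epoch: total seizure time is the summed overlap with the epoch (events
split at epoch edges); count and mean duration attribute an edge-spanning
event, with its full duration, to the epoch containing its start — counts
stay integral and time is conserved. Zero-seizure epochs have missing mean
duration. Normalization is two-step: each treatment-epoch value as a
percentage of the animal's control-period per-epoch mean, then as a
percentage of the vehicle-group mean at the matching epoch; the vehicle
group therefore averages to exactly 100% at every epoch (a tested fixed
point). "Overall" effects are means over treatment epochs within animal,
then mean ± SEM across animals — the aggregation consistent with reported
group-level mean ± SEM values; the alternative (pooling epochs) is not
used.

Statistics follow the published battery: non-repeated-measures two-way
ANOVA (drug × time) on the control-normalized values, with a marginal
(type-III-style, sum-to-zero contrasts) decomposition because arms are
unbalanced; Dunnett contrasts of each drug arm against vehicle on
animal-level treatment means; Sidak-adjusted per-epoch drug-vs-vehicle
unpaired t-tests (adjusted across the six treatment epochs within an arm);
and a pooled-variance unpaired t-test for peak frequency. Sidak adjustment
is the closed form `1 − (1 − p)^m`. Under the null generator the
per-epoch Sidak procedure is conservative (family-wise error ≈ 0.02 at
nominal 0.05 in 1000-replicate calibration runs), as expected with
positively correlated epochs.

## The synthetic generator

The generator is phenomenological: it emulates the *statistics* a real
session presents to this analysis chain, not thalamocortical biophysics.

**Background.** Five band-limited 1/f-shaped noise components (edges at
0.5, 4.5, 8.5, 12.5, 30.5, 80.5 Hz) with awake SDs 18, 16, 12, 9, 7 µV —
a desynchronized wake spectrum, total SD ≈ 31 µV after DC removal. A
wake/non-REM schedule (exponential episode lengths, default 15% non-REM)
multiplies the delta component by 2.5 during non-REM and inserts 11–13 Hz
spindle bursts (0.5–1.5 s, ~3× background SD, 4/min), labeled in the
ground truth. Movement artifacts are 0.2–0.6 s broadband bursts (350 µV
envelope, 0.2/min).

**Seizures.** Starts follow an inhomogeneous Poisson process (baseline
0.75/min) thinned by a 5 s refractory gap after each seizure; durations are
gamma, moment-matched to mean 16.1 s and SD 14.3 s, truncated at 1 s
(truncation raises the realized mean to ≈ 16.7 s). The waveform is one
sharp Gaussian spike per cycle (default 250 µV, ≈ 8× the DC-removed
background SD, comfortably above the default 6 SD threshold) followed
within the cycle by a harmonic-sharpened wave trough (150 µV fundamental),
with a 0.2 s onset/offset ramp. The trough trails the spike by 0.2 cycle so
that its threshold crossings collapse into the spike's peak — as in real
SWDs, one complex yields one peak. The fundamental dominates the wavelet
spectrum, so the ridge reads back the cycle frequency to within the grid
step.

**Drug effects.** Every effect is zero before injection, rises linearly
over 300 s (effects in this class of experiments develop within the first
20-min bin) and then holds: a rate multiplier, a duration multiplier, a
cycle-frequency shift, and per-band background amplitude multipliers.

**Preset solving.** Shipped presets (`tcb2_*`, `m100_*`, `cp_*`,
`lorcaserin_*`, `mdl_0.5`, `sb_0.5`, combinations) embed published overall
effect sizes by solving the plateau multipliers numerically so that the
*expected measured* normalized metric equals the printed value under the
study conditions. Three corrections make that expectation accurate:

- **Refractory thinning**: the realized seizure rate is
  `λ/(1 + λ(D + R))` for nominal rate λ, mean duration D and refractory R;
  the solver inverts this so count and total-time effects are recovered at
  the printed size rather than attenuated.
- **Event-weighted frequency shift**: treatment-period SWDs during the
  onset window carry only part of the shift but occur at the
  (higher) ramping rate, and seizures too short to survive the 1 s duration
  filter (effective floor ≈ 1.25 s of true duration, the filter plus ramp
  time below threshold) never contribute a frequency; the shift is solved
  against that event mix.
- **Spectral leakage**: the ~1 Hz Gaussian analysis window mixes scaled
  and unscaled band components at band edges, diluting measured power
  ratios; band amplitude multipliers are solved through the measurement
  operator (component 1/f spectra smeared by the window's power kernel).

A stationary effect model cannot embed all printed metrics of arms whose
real effect was time-varying: for `lorcaserin_3` the printed overall
total-time change (−10.1%) was biphasic and is inconsistent with the
printed count (−53.6%) and duration (+201%) effects, so that preset embeds
count and duration; for `m100_0.5` count and duration are embedded and the
implied total-time change (≈ +36%) differs from the printed +31.7%. The
`sb_lorcaserin_3` combination is shipped with qualitative multipliers (the
source reports only a partial block, without numbers).

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: no circadian structure or state-dependent seizure
probability (SWDs are inserted independently of the sleep schedule); no
waveform variability between animals or drift within a seizure; no
electrode artifacts correlated with seizures; spindle amplitudes are fixed
below threshold, so the frequency criterion's spindle rejection is
exercised at the unit level rather than end to end. Recovery of effect
sizes on this generator validates the *pipeline's bookkeeping and
estimators*, not detector performance on pathological real-world
recordings.

## Numerical choices and degenerate inputs

- Time intervals are half-open `[start, end)` in session seconds
  everywhere; event times are stored at 1 ms resolution.
- Sampling rates: simulations default to 256 Hz (all structure of interest
  is below 100 Hz; native 1000 Hz recordings are supported on read).
- Ridge ties break toward the lower frequency; an all-zero segment returns
  the lowest grid frequency (flagged only by its zero power).
- Degenerate baselines (zero variance) are an error; a baseline interval
  overlapping known seizures only warns, since the user may intend it.
- EDF output quantizes to 16 bits over each channel's physical range;
  the float32 raw format with JSON sidecar is lossless to single
  precision. Both round-trip in tests.
- `set.seed` is applied once per session from the experiment seed
  (`seed·10000 + animal index`), making cohorts reproducible and
  animal-level parallelism safe.

## Problem sizes used by the test and acceptance suites

Unit tests run on a shrunk design (two control + six treatment epochs of
300 s, 128 Hz). The recovery suites use the full −40..+120 min timeline at
256 Hz with cohorts matching the published group sizes (6–11 animals per
arm, ~1000 ground-truth seizures across a vehicle pool of 11 sessions;
vehicle sessions are shared between comparisons, which is legitimate for
independent in-silico arms). Statistical calibration runs 1000 null
replicates at the point-process level with reduced-length epochs. A full
acceptance run takes a few minutes on one CPU.

## Known limitations

- The detector is single-channel; no multichannel consensus.
- The duration filter's interaction with the onset ramp censors true
  durations below ≈ 1.25 s; recovered mean durations are accordingly ~2–3%
  above the distribution mean (well inside the acceptance tolerance, and
  inherent to threshold detection).
- Band power uses absolute spectral density; relative (total-power-
  normalized) variants are not implemented.
- The ANOVA layer treats animal × epoch cells as independent observations
  (the published design); no repeated-measures or mixed-effects option.
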