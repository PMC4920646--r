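# swdquant

Detection, spectral analysis and quantification of spike-and-wave
discharges (SWDs) in rodent EEG.

Rat models of absence epilepsy — GAERS, WAG/Rij — express frequent
spontaneous absence seizures whose EEG signature is a rhythmic ~5–12 Hz
spike-and-wave train. Pharmacology studies in these models follow a
standard analysis: detect SWDs semi-automatically, quantify **total
seizure time**, **seizure count** and **mean seizure duration** in 20-min
epochs around a drug injection at t = 0 (40-min control period before,
2-h treatment period after), normalize each animal to its control period
and to the vehicle group, estimate each SWD's **peak frequency** from a
Morlet wavelet ridge (5–14 Hz), and track **interictal band power**
(delta 1–4, theta 5–8, alpha 9–12, beta 13–30, gamma 31–80 Hz with
48–52 Hz excluded) after masking seizures, artifacts and sleep.
`swdquant` implements that chain for analysts working with this kind of
data, plus a synthetic GAERS-like session generator with ground-truth
annotations so the whole pipeline is testable end to end.

## The core algorithms

**Detection** (on the DC-removed signal, time constant 0.1 s): crossings
of a threshold *mean ± k·SD* (k ∈ [5, 9], default 6) of an awake
interictal baseline are collapsed so one spike-wave complex gives one
peak; a putative SWD opens when two peaks are < 0.2 s apart, extends
while gaps are < 0.4 s, events < 0.5 s apart are amalgamated, events
< 1 s discarded, and an event is accepted iff ≥ 75% of its instantaneous
frequencies 1/Δt lie in 5–12 Hz — which discriminates SWDs from sleep
spindles and artifacts.

**Ictal frequency**: analytic Morlet CWT (resolution parameter f0 = 1) on
a 0.1 Hz grid, 5–14 Hz; per-SWD mean of the power-maximum ridge;
per-animal unweighted mean over treatment-period SWDs.

**Interictal power**: FIR anti-aliased resampling to 200 Hz, sample
masking, Gaussian-window STFT (~1 Hz resolution) on integer bins 1–80 Hz
per 20-min epoch, band means with the mains notch excluded from gamma.

**Statistics**: two-way ANOVA (drug × time, type-III, unbalanced arms),
Dunnett contrasts vs vehicle on animal-level treatment means,
Sidak-adjusted per-epoch contrasts, pooled unpaired t-tests for peak
frequency.

The generator embeds published drug-effect sizes as solved presets
(`tcb2_3`, `lorcaserin_3`, `m100_0.5`, `cp_10`, ...): plateau multipliers
for seizure rate, duration, cycle frequency and band amplitudes are
solved numerically so the pipeline reads the printed overall percentages
back out. See the methods vignette (`vignettes/swd-analysis.Rmd`).

## Worked example

Simulate one animal given a mid-dose 5-HT2A-agonist preset, detect its
seizures, and quantify them per epoch:

```r
library(swdquant)

ses <- assemble_session(preset = "tcb2_0.3", fs = 256, seed = 42)
events <- detect_swds(ses$rec, baseline = "auto", events = ses$ground_truth)
str(attr(events, "report"))
#> $ baseline_interval: num [1:2] -1157 -1037
#> $ baseline_sd_uv   : num 25.6
#> $ n_peaks          : int 5888
#> $ n_putative       : int 88
#> $ n_min_duration   : int 56
#> $ n_accepted       : int 56

epoch_metrics(events)
#>   epoch_index total_seizure_time_s n_seizures mean_seizure_duration_s
#> 1          -2              319.607         18               17.755944
#> 2          -1              200.222         13               15.401692
#> 3           0               62.946          6               10.491000
#> 4           1               57.599          7                8.228429
#> ...
```

The two control epochs (−2, −1) show the unperturbed seizure load
(~260 s per 20 min); after the injection at t = 0 the preset's solved rate
and duration multipliers cut total seizure time to roughly 30% of control,
the embedded published effect for this dose. A cohort-level run wraps
this per-animal loop and the normalization/statistics:

```r
ex <- run_experiment(c(vehicle = 9, tcb2_0.3 = 9), what = "metrics", seed = 1)
nm <- normalize_metrics(ex$metrics)
overall_effect(nm, "tcb2_0.3", "total_time")   # ~69% overall decrease vs vehicle
anova_two_way(nm, "total_time")                # drug x time ANOVA + post hocs
```

A thin command-line front end covers the same steps
(`inst/cli/swdquant.R`: `simulate`, `detect`, `ictal`, `interictal`,
`quantify`, `run-all`), reading/writing EDF or float32 recordings and CSV
event files.

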