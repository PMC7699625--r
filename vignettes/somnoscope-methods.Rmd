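---
title: "Simulating and analyzing mouse sleep recordings with somnoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing mouse sleep recordings with somnoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoscope)
```

## What this package is for

Rodent sleep studies score chronic EEG/EMG recordings into 4-second epochs
of wakefulness (WAKE), non-REM sleep (NREM), REM sleep and — in narcoleptic
models — cataplexy, and then quantify two complementary layers:

* **architecture**: how much of each state occurs and when (minutes per
  hour across the light/dark cycle), how fragmented it is (bouts and their
  duration distribution), how fast REM sleep is reached after sleep onset,
  and how often the animal transitions into and out of REM;
* **spectral content**: per-epoch EEG power spectra, state-specific mean
  spectra normalized to a per-animal baseline reference, and the dynamics
  of band power (above all NREM delta, the standard index of homeostatic
  sleep pressure) across baseline days, a 6-h sleep deprivation (SD), and
  recovery.

`somnoscope` implements this full analysis stack, plus two signal-level
classifiers used in hypocretin (HCRT)-deficient models — theta-dominated
wakefulness (TDW) and cataplexy detection — and, crucially, a simulator
that generates scored recordings with known ground truth so that every
stage can be validated without animal data.

## The simulator

### State sequence

`simulate_hypnogram()` draws vigilance states on the 4-s epoch grid from a
semi-Markov chain. WAKE alternates with NREM; REM is reachable only from
NREM (probability `p_rem_entry` per NREM bout ending) and exits to WAKE or
NREM (`p_rem_exit_wake`); cataplexy arises only out of WAKE, only after at
least 40 s of continuous prior wakefulness, with a per-hour-of-wake rate,
and returns to WAKE. Dwell times are geometric in epochs. The geometric
choice is deliberate: it is the memoryless law, so the whole process
collapses to a per-epoch transition rule (leave the current state with
probability `4 s / mean dwell`), which makes the light/dark switching of
all rates at ZT0/ZT12 exact rather than approximate, and it produces the
heavy-tailed bout-duration histograms that bout analyses bin on a
log-spaced axis. Nothing in the analysis stack assumes this law.

Because the embedded jump chain of the three main states has a closed-form
stationary distribution (weights `1 - p + p*q, 1, p` for WAKE/NREM/REM,
with `p = p_rem_entry`, `q = p_rem_exit_wake`), long-run simulated state
fractions can be checked against `stationary_occupancy()` — an independent
analytic oracle that the test suite exercises at 30 simulated days with a
3-Monte-Carlo-SE criterion.

### Homeostasis

`process_s()` implements the classic two-process recursion per epoch:
S rises toward 1 as `S <- 1 - (1 - S) exp(-dt/tau_rise)` during WAKE, REM
and cataplexy and decays as `S <- S exp(-dt/tau_decay)` during NREM, with
defaults `tau_rise = 8 h`, `tau_decay = 2 h` — the magnitudes classically
fitted to rodent delta power. S is dimensionless in [0, 1], bounded and
piecewise monotone by construction.

### Signals

`synthesize_signals()` renders each epoch as 1/f background noise plus
state-gated sinusoidal oscillators with fresh random phase per epoch:
NREM delta at 2.25 Hz with amplitude proportional to `sqrt(S)` (so delta
*power* tracks S linearly), a theta oscillator at the preset's
`theta_peak_hz` in REM, cataplexy and TDW-flagged wake epochs, a slow
2.5 Hz component in quiet wake, and weak gamma components. All oscillator
frequencies sit on the 0.25 Hz bin grid, so with 4-s epochs and a
rectangular window each oscillator occupies exactly one DFT bin — this is
what makes planted-value recovery tests exact. The default sampling rate
of 200 Hz gives the native 0.25 Hz resolution with no padding and reaches
90 Hz with margin; any `fs >= 180` is accepted.

The EMG channel is white noise with per-state RMS (defaults 40 uV WAKE,
15 NREM, 4 REM and cataplexy). REM epochs additionally receive a
lognormal per-epoch modulation (`emg_rem_twitch_sd = 0.25`): murine REM
atonia is punctuated by phasic muscle twitches, so between-epoch REM EMG
variance is real signal, whereas cataplexy atonia is tonic and flat. This
matters for detection: the atonia threshold is self-calibrated as
`mean + 2 SD` of per-epoch REM EMG RMS, and it is precisely the phasic
REM variability that places that threshold well above the tonic atonia
floor. A simulator without twitches would make the threshold pathologically
tight (2 estimation-SEs above the floor) and split detected episodes on
single-epoch fluctuations.

### Genotype presets

`genotype_presets()` ships five parameter sets — `WT`, `HcrtKO`,
`X5HTTKO`, `X5HTThet_HcrtKO`, `DKO` — encoding direction-of-effect
contrasts between wild-type and hypocretin/serotonin-transporter mutants:
more light-period REM when 5HTT is absent, more dark-period REM and
frequent cataplexy when HCRT is absent, a much lower cataplexy rate and a
fast (8.25 Hz) REM theta peak in the double knockout, and zero cataplexy
whenever HCRT is intact. The magnitudes are simulator parameters chosen
once to be physiologically plausible for C57BL/6-background mice (e.g.
WT light-period occupancies of roughly 41% wake / 52% NREM / 7% REM);
they are not measurements, and no analysis in the package depends on
their exact values.

What the simulator does **not** emulate: within-state spectral
nonstationarity (real delta power fluctuates within a NREM bout),
circadian modulation beyond the binary light/dark switch, scoring errors
and ambiguous transition epochs, movement and electrode artifacts with
realistic spectra (artifacts are label flags only), and volume-conduction
or channel-referencing effects. Passing tests therefore demonstrate the
*analytics* are correct for signals obeying the stated model, not that
the model exhausts real mouse EEG.

## Analysis conventions

* **Epochs** are 4 s everywhere; spectra are one-sided, 0-90 Hz at
  0.25 Hz (361 bins), scaled so that a bin-aligned sinusoid of amplitude
  `a` contributes `a^2/2` to its bin and total power obeys Parseval when
  the grid reaches Nyquist. The window is rectangular by default — the
  direct per-epoch DFT convention of commercial scoring software — with a
  Hanning taper available (`epoch_spectra(taper = "hanning")`); the two
  differ only in spectral leakage of non-bin-aligned components.
* **Scorable epochs** for any spectral average are artifact-free epochs
  whose two neighbours share their state and are also artifact-free
  (`select_scorable_epochs()`). Architecture statistics deliberately keep
  artifact epochs: an artifact corrupts the signal, not the state label.
* **Band edges are inclusive** on both sides (`band_power()` sums
  `lo <= f <= hi`). The canonical band list (`eeg_bands()`) uses
  non-contiguous adjacent bands (slow-delta 1-2 Hz, fast-delta 3-4 Hz),
  which is what makes inclusive integer edges the consistent reading;
  bands that do share an edge double-count exactly that one bin.
* **Normalization** follows the state-weighted baseline-reference scheme:
  for each mouse, total 0.75-47.5 Hz power on baseline day one is
  averaged per state over scorable epochs and combined across
  WAKE/NREM/REM with cohort-level weights
  (`cohort_state_weights()`), so differences in state *amounts* between
  mice do not leak into their references; spectra are then expressed as
  percent of this value. For a cohort of identical mice the weights
  cancel and the reference degenerates to the mouse's own pooled mean —
  a property the tests assert.
* **Theta peak frequency** is the argmax bin of the REM mean spectrum
  searched over 5-10 Hz. The search window is deliberately wider than the
  6-8 Hz theta-peak band itself because fast-peak genotypes (the `DKO`
  preset plants 8.25 Hz) fall outside 6-8; ties break toward the lower
  frequency.
* **TDW**: a wake epoch is theta-dominated when its spectral argmax over
  0.75-12 Hz lies in 6.0-9.5 Hz. Non-wake epochs are never TDW.
* **Cataplexy detection** requires >= 12 s (3 epochs) of wake-scored,
  atonic, theta-dominated EEG directly preceded by >= 40 s of
  supra-threshold (active) wakefulness; runs interrupted by a single
  non-qualifying epoch are not merged. The duration and precedence
  values follow the consensus murine cataplexy definition; both are
  arguments of `detect_cataplexy()`.

### REM latency

Latency is measured from sleep onset — the first NREM run of at least 3
consecutive epochs whose immediately preceding non-NREM stretch contains
at least one WAKE epoch — to the first subsequent run of at least 2
consecutive REM epochs. Two readings of "per-period latency" are
defensible: the first event only, or the mean over all events. The
package computes **every** event in the period (a new onset is armed only
after the previous event found its REM pair) and returns the mean plus
the raw per-event latencies, so either summary is available; periods with
no completed event return `NA`, never zero. Cataplexy epochs neither
constitute the required prior wakefulness nor interrupt a NREM run's
count, and no minimum prior-wake duration gates onset (the consolidation
criterion is the 3-epoch NREM run itself).

### Percentile time-courses

`band_power_timecourse()` reproduces the equal-occupancy percentile
convention: within each interval the state's scorable epochs are split
into contiguous groups whose sizes differ by at most one (remainder to
the earliest groups), the band power is averaged per group, and values
are normalized either to the state's own baseline mean (mode A) or, for
NREM delta, to the mean delta power in baseline ZT8-12 (mode B) — the
late-light floor that serves as the 100% anchor for SD rebound plots.
Percentile counts are 12 (light), 6 (dark) and 8 (post-SD light) for
NREM and REM, and 6/12/8/4 for wake including the SD window itself.
The recovery dark period is not given its own count in the published
scheme; the package reuses the dark counts (6 for sleep states, 12 for
wake), which keeps epoch occupancy per percentile comparable across dark
periods. Baseline days can be averaged percentile-by-percentile with
`average_baselines()`.

## Numerical and degenerate-input choices

* Empty spectral selections return `NA` vectors with a warning — a state
  absent from an interval is *undefined*, not zero power.
* A flat spectrum in the TPF search band warns and returns the band's
  lower edge (the tie-break rule applied to total degeneracy).
* Intervals with fewer scorable epochs than percentiles yield `NA`
  percentile rows rather than an error, so one sparse interval does not
  abort a mouse.
* `partition_percentiles()` errors if any group would be empty.
* EDF I/O quantizes to 16 bits over a symmetric physical range; the
  round-trip error bound `(phys range)/65535/2` is asserted in tests.
  Truncated files and missing channels are parse errors, never partial
  objects.
* All randomness flows through explicit integer seeds; two runs of
  `run_pipeline()` with the same configuration are byte-identical.

## Problem sizes used in validation

The shipped test-and-acceptance workloads use one simulated mouse per
role: a 3-day wild-type protocol (2 baseline days, SD on day 3) for the
homeostasis and normalization checks, a 2-day narcoleptic recording for
cataplexy/TDW recovery, 30 hypnogram-only days for stationary-occupancy
convergence, and 200-1000 short random hypnograms for the brute-force
oracle comparisons. These sizes put every Monte-Carlo criterion (3 SE for
occupancy, >= 95% episode recovery) comfortably inside its noise budget
while keeping a full validation run in the minutes range on one core.

## Worked example

```{r example, eval = FALSE}
p <- genotype_presets("WT")
hyp <- simulate_hypnogram(p, days = 3, seed = 1)
hyp <- apply_sleep_deprivation(hyp, day = 3)          # ZT0-6 enforced wake
hyp <- mark_artifacts(hyp, 0.02, seed = 2)
rec <- synthesize_signals(hyp, p, seed = 3)
sp  <- epoch_spectra(rec)

## REM architecture in the baseline dark period
rem <- detect_bouts(hyp, "REM")
long_rem_bout_count(rem)
rems_latency(hyp, epochs_in(hyp, 1, 12, 24)[1],
             max(epochs_in(hyp, 1, 12, 24)))$mean

## homeostatic delta dynamics, anchored at baseline ZT8-12 = 100%
tc <- band_power_timecourse(sp, hyp, "NREM", eeg_bands("delta"),
                            mode = "zt8_12_delta", sd_day = 3)
head(average_baselines(tc))
```

For a cohort, `run_config()` + `run_pipeline()` simulate (or load from
EDF/TSV), analyze every mouse and write tidy CSV tables including a
per-genotype descriptive summary (mean, SD, SEM). Inferential statistics
are intentionally out of scope: the package emits the per-mouse and group
descriptive tables that a statistics environment then consumes.

## Known limitations

* The simulator's dwell law is geometric; real bout-duration
  distributions mix short and long regimes beyond a single geometric.
* Cataplexy detection validates against the simulator's operational
  definition; against video-truth data the thresholds would need
  re-tuning, which is why all of them are exposed as arguments.
* The EDF layer writes the minimal two-channel subset of the format, not
  EDF+ annotations.
* Epoch indices in R interfaces are 1-based; serialized TSVs use 0-based
  `epoch_index`. Mixing the two is the main foot-gun when interoperating
  with external tooling.
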