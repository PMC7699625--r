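# somnoscope

Mouse polysomnography simulation and sleep-EEG analytics in R.

Chronic mouse EEG/EMG studies score recordings into 4-s epochs of
wakefulness, NREM sleep, REM sleep and — in narcoleptic models —
cataplexy, then quantify state architecture and spectral dynamics across
baseline days, a 6-h sleep deprivation (SD) and recovery. `somnoscope`
is for sleep researchers and methods developers who need that analysis
stack as tested, reusable code, together with a ground-truth simulator
so every stage can be validated without animal data.

## What it computes

**Architecture** (from the hypnogram alone)

- state time-courses in min/h, 2-h windows, baseline days averaged
- bouts (maximal same-state runs), duration histograms on lower-edge
  bins (8, 16, 32, 64, 128, 256 s), long-REM-bout (>2 min) counts
- REM-sleep latency: from sleep onset (first NREM run of ≥3 epochs
  preceded by wakefulness) to the first ≥2-epoch REM run
- transitions into and out of REM, by destination state

**Spectra** (per 4-s epoch, rectangular-window DFT, 0–90 Hz @ 0.25 Hz)

- artifact-free, same-state-flanked epoch selection
- state mean spectra as % of a per-mouse baseline reference: total
  0.75–47.5 Hz power on baseline day 1, combined over WAKE/NREM/REM
  with cohort-level state weights so every mouse's reference has the
  same state composition
- band powers with inclusive edges (delta 1–4, slow-delta 1–2 /
  0.75–2.5 / 0.75–1, fast-delta 3–4, theta 6.5–8.5, TDW 6.0–9.5,
  slow-gamma 32–45, fast-gamma 55–80 Hz)
- REM theta peak frequency (argmax in 5–10 Hz, ties break low)
- equal-occupancy percentile time-courses (12/6/8 percentiles for sleep
  states in light/dark/post-SD, 6/12/8/4 for wake), normalized to the
  state's baseline mean or to NREM delta in baseline ZT8–12 = 100 %

**Classifiers**

- theta-dominated wakefulness (TDW): wake epochs whose spectral argmax
  over 0.75–12 Hz falls in 6.0–9.5 Hz
- cataplexy: ≥12 s of wake-scored, atonic (EMG RMS below a
  self-calibrated REM-based threshold), theta-dominated EEG preceded by
  ≥40 s of active wakefulness

**Simulator**

- semi-Markov hypnograms (REM only from NREM; cataplexy only out of
  sustained wakefulness; geometric dwells; light/dark rate switching),
  with an analytic stationary-occupancy oracle for validation
- two-process homeostat (Process S: exponential rise in wake, decay in
  NREM) driving the NREM delta amplitude
- state-gated EEG/EMG synthesis: 1/f background plus bin-aligned
  oscillators (delta ∝ √S in NREM, theta in REM/TDW/cataplexy), EMG
  atonia with phasic REM twitches
- five genotype presets (`WT`, `HcrtKO`, `X5HTTKO`, `X5HTThet_HcrtKO`,
  `DKO`) encoding direction-of-effect contrasts (no cataplexy with
  intact HCRT, fast 8.25 Hz REM theta peak in `DKO`, ...)

I/O: minimal two-channel EDF read/write, hypnogram TSV, YAML run
configurations, tidy CSV outputs, and a deterministic end-to-end
`run_pipeline()`.

## Worked example

```r
library(somnoscope)

p   <- genotype_presets("WT")
hyp <- simulate_hypnogram(p, days = 3, seed = 1)     # 2 baseline days + day 3
hyp <- apply_sleep_deprivation(hyp, day = 3)         # enforced wake ZT0-6
hyp <- mark_artifacts(hyp, 0.02, seed = 2)
rec <- synthesize_signals(hyp, p, seed = 3)          # EEG + EMG at 200 Hz
sp  <- epoch_spectra(rec)                            # 64800 x 361 spectra

rem <- detect_bouts(hyp, "REM")
nrow(rem)                                            # 153 REM bouts
long_rem_bout_count(rem)                             # 20 bouts > 2 min

d1_dark <- epochs_in(hyp, day = 1, zt_from = 12, zt_to = 24)
rems_latency(hyp, min(d1_dark), max(d1_dark))$mean   # 1898 s

idx <- select_scorable_epochs(hyp, "REM")
theta_peak_frequency(state_mean_spectrum(sp, idx))   # 7.25 Hz (planted)

tc <- band_power_timecourse(sp, hyp, "NREM", eeg_bands("delta"),
                            mode = "zt8_12_delta", sd_day = 3)
head(average_baselines(tc), 4)
#>         interval day percentile n_epochs zt_center value_percent
#> 1 baseline_light  NA          1      433    0.4154         222.0
#> 2 baseline_light  NA          2      433    1.1282         183.5
#> 3 baseline_light  NA          3      433    2.2425         159.7
#> 4 baseline_light  NA          4      433    3.4081         147.1
```

NREM delta power starts the light period high (~220 % of the ZT8–12
reference, the homeostatic pressure accumulated over the dark period)
and declines toward the 100 % late-light floor; after sleep deprivation
the first recovery percentile rebounds to ~336 % — the classic
homeostatic signature, here recovered from the synthesized signals
rather than assumed.

For a cohort:

```r
cfg <- run_config(out_dir = "out", genotypes = c("WT", "HcrtKO", "DKO"),
                  n_per_genotype = 4, days = 3, sd_day = 3, seed = 1)
run_pipeline(cfg)   # tidy CSVs incl. per-genotype descriptive summary
```

A thin CLI over the same functions lives in `inst/cli/somnoscope.R`
(`simulate` and `analyze` subcommands).

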