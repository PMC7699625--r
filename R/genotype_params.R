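#' Simulator parameter set for one genotype
#'
#' Bundles every knob of the polysomnography simulator: semi-Markov state
#' dwell means per light phase, REM-entry and REM-exit branching
#' probabilities, cataplexy propensity, state-gated oscillator amplitudes,
#' theta peak frequency, two-process (Process S) time constants and
#' per-state EMG tone.
#'
#' Dwell times are geometric on the 4-s epoch grid, so `dwell_mean` values
#' are mean bout durations in seconds (minimum one epoch). Cataplexy can
#' only be generated when `cataplexy_rate > 0`; presets with an intact
#' hypocretin (HCRT) system must keep it at 0.
#'
#' @param name Label for the parameter set.
#' @param dwell_mean Named list `list(light = c(WAKE=, NREM=, REM=), dark = ...)`
#'   of mean dwell times in seconds.
#' @param p_rem_entry Named numeric `c(light=, dark=)`: probability that a
#'   NREM bout ends into REM rather than WAKE.
#' @param p_rem_exit_wake Named numeric `c(light=, dark=)`: probability that
#'   a REM bout ends into WAKE rather than NREM.
#' @param cataplexy_rate Named numeric `c(light=, dark=)`: expected cataplexy
#'   episodes per hour of wakefulness.
#' @param cataplexy_dwell_mean Mean cataplexy episode duration, seconds
#'   (minimum enforced at 12 s = 3 epochs).
#' @param theta_peak_hz Planted REM/TDW theta oscillator frequency in Hz;
#'   must lie in 5-10 Hz and on the 0.25 Hz bin grid.
#' @param tdw_prob Named numeric `c(light=, dark=)`: probability that a WAKE
#'   epoch is theta-dominated (TDW).
#' @param band_gains Named list of per-state oscillator amplitudes (uV), see
#'   [synthesize_signals()].
#' @param noise_amp Amplitude scale of the 1/f EEG background noise (uV).
#' @param s_tau_rise,s_tau_decay Process-S time constants in hours (rise
#'   during WAKE/REM/cataplexy, decay during NREM).
#' @param emg_rms Named numeric per-state EMG root-mean-square amplitude in
#'   uV; REM and cataplexy values must be well below NREM and WAKE (atonia).
#' @param emg_rem_twitch_sd Log-scale SD of the per-epoch phasic (twitch)
#'   modulation of REM EMG; cataplexy atonia is tonic (no modulation).
#'
#' @return An object of class `genotype_params`.
#' @seealso [genotype_presets()], [simulate_hypnogram()], [synthesize_signals()]
#' @export
genotype_params <- function(name,
                            dwell_mean,
                            p_rem_entry,
                            p_rem_exit_wake = c(light = 0.7, dark = 0.7),
                            cataplexy_rate = c(light = 0, dark = 0),
                            cataplexy_dwell_mean = 40,
                            theta_peak_hz = 7.25,
                            tdw_prob = c(light = 0.25, dark = 0.45),
                            band_gains = default_band_gains(),
                            noise_amp = 6,
                            s_tau_rise = 8,
                            s_tau_decay = 2,
                            emg_rms = c(WAKE = 40, NREM = 15, REM = 4, CATAPLEXY = 4),
                            emg_rem_twitch_sd = 0.25) {
  phases <- c("light", "dark")
  states3 <- c("WAKE", "NREM", "REM")
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(phases %in% names(dwell_mean)))
    stop("dwell_mean must have 'light' and 'dark' entries")
  for (ph in phases) {
    dm <- dwell_mean[[ph]]
    if (!all(states3 %in% names(dm)))
      stop("dwell_mean$", ph, " must name WAKE, NREM and REM")
    if (any(!is.finite(dm[states3])) || any(dm[states3] < 4))
      stop("all dwell means must be finite and >= one 4-s epoch")
  }
  chk_prob <- function(p, what) {
    if (!all(phases %in% names(p)) || any(p[phases] < 0) || any(p[phases] > 1))
      stop(what, " must be probabilities named light/dark in [0,1]")
  }
  chk_prob(p_rem_entry, "p_rem_entry")
  chk_prob(p_rem_exit_wake, "p_rem_exit_wake")
  chk_prob(tdw_prob, "tdw_prob")
  if (any(cataplexy_rate[phases] < 0))
    stop("cataplexy_rate must be non-negative")
  if (cataplexy_dwell_mean < 12)
    stop("cataplexy_dwell_mean must be >= 12 s (3 epochs)")
  if (theta_peak_hz < 5 || theta_peak_hz > 10)
    stop("theta_peak_hz must lie within 5-10 Hz")
  if (abs(theta_peak_hz / 0.25 - round(theta_peak_hz / 0.25)) > 1e-9)
    stop("theta_peak_hz must be a multiple of 0.25 Hz (bin-aligned)")
  if (any(emg_rms[c("REM", "CATAPLEXY")] >= emg_rms["NREM"]) ||
      emg_rms["NREM"] >= emg_rms["WAKE"])
    stop("emg_rms must satisfy REM = CATAPLEXY < NREM < WAKE ordering")
  structure(list(
    name = name,
    dwell_mean = dwell_mean,
    p_rem_entry = p_rem_entry,
    p_rem_exit_wake = p_rem_exit_wake,
    cataplexy_rate = cataplexy_rate,
    cataplexy_dwell_mean = cataplexy_dwell_mean,
    theta_peak_hz = theta_peak_hz,
    tdw_prob = tdw_prob,
    band_gains = band_gains,
    noise_amp = noise_amp,
    s_tau_rise = s_tau_rise,
    s_tau_decay = s_tau_decay,
    emg_rms = emg_rms,
    emg_rem_twitch_sd = emg_rem_twitch_sd
  ), class = "genotype_params")
}

#' Default per-state oscillator amplitudes
#'
#' Amplitudes (uV) of the state-gated sinusoidal components of the synthetic
#' EEG. The NREM delta amplitude is further scaled by `sqrt(Process S)` at
#' synthesis time so that NREM delta *power* tracks homeostatic sleep
#' pressure. Gamma amplitudes are kept small relative to delta/theta, as in
#' real rodent EEG where gamma power is orders of magnitude below delta.
#'
#' @return Named list with entries `NREM` (`delta`), `REM` (`theta`,
#'   `slow_gamma`), `CATAPLEXY` (`theta`), `WAKE_TDW` (`theta`, `slow_gamma`,
#'   `fast_gamma`) and `WAKE_QUIET` (`slow`, `slow_gamma`).
#' @export
default_band_gains <- function() {
  list(
    NREM = c(delta = 40),
    REM = c(theta = 30, slow_gamma = 4),
    CATAPLEXY = c(theta = 30),
    WAKE_TDW = c(theta = 25, slow_gamma = 5, fast_gamma = 4),
    WAKE_QUIET = c(slow = 12, slow_gamma = 4, fast_gamma = 3)
  )
}

#' Genotype presets for the simulator
#'
#' Five parameter sets encoding the direction-of-effect contrasts between
#' wild-type mice and hypocretin (HCRT) / serotonin-transporter (5HTT)
#' mutants: `WT`, `HcrtKO` (narcoleptic: frequent cataplexy, fragmented dark
#' -period wakefulness, more dark-period REM), `X5HTTKO` (intact HCRT, no
#' cataplexy, strongly increased light-period REM), `X5HTThet_HcrtKO`
#' (cataplexy like `HcrtKO`) and `DKO` (double knockout: high REM in both
#' phases, much rarer cataplexy, fast 8.25 Hz theta peak). Magnitudes are
#' simulator parameters, not biological measurements.
#'
#' @param name Optional preset name; omit to get the full named list.
#' @return A `genotype_params` object, or a named list of all five.
#' @examples
#' p <- genotype_presets("WT")
#' p$theta_peak_hz
#' @export
genotype_presets <- function(name = NULL) {
  presets <- list(
    WT = genotype_params(
      name = "WT",
      dwell_mean = list(
        light = c(WAKE = 200, NREM = 220, REM = 70),
        dark = c(WAKE = 600, NREM = 180, REM = 60)
      ),
      p_rem_entry = c(light = 0.45, dark = 0.25),
      theta_peak_hz = 7.25
    ),
    HcrtKO = genotype_params(
      name = "HcrtKO",
      dwell_mean = list(
        light = c(WAKE = 180, NREM = 220, REM = 70),
        dark = c(WAKE = 280, NREM = 180, REM = 70)
      ),
      p_rem_entry = c(light = 0.45, dark = 0.4),
      cataplexy_rate = c(light = 0.4, dark = 2.5),
      theta_peak_hz = 7.5,
      tdw_prob = c(light = 0.25, dark = 0.3)
    ),
    X5HTTKO = genotype_params(
      name = "X5HTTKO",
      dwell_mean = list(
        light = c(WAKE = 200, NREM = 210, REM = 95),
        dark = c(WAKE = 600, NREM = 180, REM = 65)
      ),
      p_rem_entry = c(light = 0.6, dark = 0.27),
      theta_peak_hz = 7.5
    ),
    X5HTThet_HcrtKO = genotype_params(
      name = "X5HTThet_HcrtKO",
      dwell_mean = list(
        light = c(WAKE = 180, NREM = 215, REM = 75),
        dark = c(WAKE = 300, NREM = 180, REM = 68)
      ),
      p_rem_entry = c(light = 0.5, dark = 0.38),
      cataplexy_rate = c(light = 0.35, dark = 2.2),
      theta_peak_hz = 7.5,
      band_gains = local({
        g <- default_band_gains()
        g$REM["theta"] <- 38  # elevated REM theta power
        g$WAKE_TDW["theta"] <- 30
        g
      }),
      tdw_prob = c(light = 0.25, dark = 0.32)
    ),
    DKO = genotype_params(
      name = "DKO",
      dwell_mean = list(
        light = c(WAKE = 190, NREM = 210, REM = 90),
        dark = c(WAKE = 350, NREM = 180, REM = 80)
      ),
      p_rem_entry = c(light = 0.55, dark = 0.45),
      cataplexy_rate = c(light = 0.1, dark = 0.5),
      theta_peak_hz = 8.25,
      band_gains = local({
        g <- default_band_gains()
        g$REM["theta"] <- 24  # blunted theta power
        g$WAKE_TDW["theta"] <- 20
        g
      }),
      tdw_prob = c(light = 0.25, dark = 0.35)
    )
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown genotype preset: ", name,
         " (available: ", paste(names(presets), collapse = ", "), ")")
  presets[[name]]
}

#' @export
print.genotype_params <- function(x, ...) {
  cat("<genotype_params>", x$name, "\n")
  cat("  dwell means (s), light:",
      paste(names(x$dwell_mean$light), x$dwell_mean$light, collapse = ", "), "\n")
  cat("  dwell means (s), dark: ",
      paste(names(x$dwell_mean$dark), x$dwell_mean$dark, collapse = ", "), "\n")
  cat("  p(REM entry) light/dark:", x$p_rem_entry["light"], "/",
      x$p_rem_entry["dark"], "\n")
  cat("  cataplexy rate (/h wake) light/dark:", x$cataplexy_rate["light"],
      "/", x$cataplexy_rate["dark"], "\n")
  cat("  theta peak:", x$theta_peak_hz, "Hz\n")
  invisible(x)
}
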