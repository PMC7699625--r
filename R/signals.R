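#' Synthesize EEG/EMG signals for a hypnogram
#'
#' Builds a two-channel recording whose per-state spectral content matches
#' what sleep-EEG analytics assume. The EEG of every 4-s epoch is a 1/f
#' (pink) background plus state-gated, bin-aligned sinusoidal oscillators
#' with a fresh random phase per epoch:
#'
#' * NREM: a delta oscillator (2.25 Hz) whose amplitude is the preset gain
#'   times `sqrt(Process S)`, so NREM delta *power* is proportional to
#'   homeostatic sleep pressure;
#' * REM and cataplexy: a theta oscillator at `params$theta_peak_hz`;
#' * WAKE epochs flagged TDW: the same theta oscillator plus weak gamma
#'   components; unflagged (quiet) WAKE: a slow 2.5 Hz component plus weak
#'   gamma.
#'
#' The EMG channel is white noise with per-state RMS `params$emg_rms`,
#' giving muscle atonia (REM = cataplexy, far below NREM < WAKE).
#' Oscillator frequencies are multiples of 0.25 Hz, so with a 4-s epoch
#' and rectangular-window DFT each oscillator lands in exactly one bin.
#'
#' @param hyp A [hypnogram()]; its `tdw` column (if any) gates the wake
#'   oscillators.
#' @param params A [genotype_params()].
#' @param fs Sampling rate in Hz, >= 180 so spectra reach 90 Hz; the
#'   default 200 gives native 0.25 Hz bins with no padding.
#' @param seed Integer seed; output is deterministic given
#'   `(hyp, params, fs, seed)`.
#' @return An object of class `psg_recording`: list with `eeg`, `emg`
#'   (uV sample vectors), `fs` and `epoch_len`.
#' @export
synthesize_signals <- function(hyp, params, fs = 200, seed = 1L) {
  stopifnot(inherits(params, "genotype_params"))
  if (fs < 180) stop("fs must be >= 180 Hz to resolve spectra up to 90 Hz")
  fs <- as.integer(fs)
  n_ep <- nrow(hyp)
  N <- EPOCH_SEC * fs
  set.seed(as.integer(seed))

  st <- as_state_chr(hyp)
  tdw <- if (!is.null(hyp$tdw)) hyp$tdw else rep(FALSE, n_ep)
  s_traj <- process_s(hyp, params$s_tau_rise, params$s_tau_decay)
  g <- params$band_gains

  # per-epoch oscillator phases, drawn up front for determinism
  two_pi <- 2 * pi
  phi <- list(
    delta = runif(n_ep) * two_pi, theta = runif(n_ep) * two_pi,
    slow = runif(n_ep) * two_pi, sgamma = runif(n_ep) * two_pi,
    fgamma = runif(n_ep) * two_pi
  )
  freqs <- c(delta = 2.25, theta = params$theta_peak_hz, slow = 2.5,
             sgamma = 38.25, fgamma = 65.25)

  # per-epoch amplitude of each oscillator component
  amp <- matrix(0, n_ep, 5, dimnames = list(NULL, names(freqs)))
  i_n <- st == "NREM"; i_r <- st == "REM"; i_c <- st == "CATAPLEXY"
  i_wt <- st == "WAKE" & tdw; i_wq <- st == "WAKE" & !tdw
  amp[i_n, "delta"] <- g$NREM["delta"] * sqrt(s_traj[i_n])
  amp[i_r, "theta"] <- g$REM["theta"]
  amp[i_r, "sgamma"] <- g$REM["slow_gamma"]
  amp[i_c, "theta"] <- g$CATAPLEXY["theta"]
  amp[i_wt, "theta"] <- g$WAKE_TDW["theta"]
  amp[i_wt, "sgamma"] <- g$WAKE_TDW["slow_gamma"]
  amp[i_wt, "fgamma"] <- g$WAKE_TDW["fast_gamma"]
  amp[i_wq, "slow"] <- g$WAKE_QUIET["slow"]
  amp[i_wq, "sgamma"] <- g$WAKE_QUIET["slow_gamma"]
  amp[i_wq, "fgamma"] <- g$WAKE_QUIET["fast_gamma"]

  # sin/cos basis per component (length-N columns)
  tt <- (seq_len(N) - 1) / fs
  basis_s <- sapply(freqs, function(f) sin(two_pi * f * tt))
  basis_c <- sapply(freqs, function(f) cos(two_pi * f * tt))

  # 1/f spectral shaping gains on the epoch DFT grid (DC removed); the
  # pink background is drawn directly in the frequency domain, scaled so
  # its per-bin power matches white noise filtered by `shape`
  fgrid <- c(0, pmin(seq_len(N - 1), N - seq_len(N - 1))) * (1 / EPOCH_SEC)
  shape <- ifelse(fgrid == 0, 0, 1 / sqrt(pmax(fgrid, 0.75)))
  half <- N %/% 2L  # N = 4*fs is even

  eeg <- numeric(n_ep * N)
  chunk <- 4096L
  for (j0 in seq(1L, n_ep, by = chunk)) {
    j1 <- min(j0 + chunk - 1L, n_ep)
    k <- j1 - j0 + 1L
    f <- matrix(0 + 0i, N, k)
    f[2:half, ] <- matrix(complex(real = rnorm((half - 1L) * k),
                                  imaginary = rnorm((half - 1L) * k)),
                          half - 1L, k) * (shape[2:half] * sqrt(N / 2))
    f[half + 1L, ] <- rnorm(k) * shape[half + 1L] * sqrt(N)
    f[(half + 2L):N, ] <- Conj(f[half:2, , drop = FALSE])
    pink <- Re(mvfft(f, inverse = TRUE)) / N * params$noise_amp
    osc <- basis_s %*% t(amp[j0:j1, , drop = FALSE] * cos(sapply(phi, `[`, j0:j1))) +
           basis_c %*% t(amp[j0:j1, , drop = FALSE] * sin(sapply(phi, `[`, j0:j1)))
    eeg[((j0 - 1L) * N + 1L):(j1 * N)] <- pink + osc
  }

  # EMG: white noise at the state RMS. REM epochs get lognormal phasic
  # modulation (muscle twitches interrupt REM atonia, epoch by epoch);
  # cataplexy atonia is tonic and stays at the flat floor.
  rms_ep <- params$emg_rms[st]
  i_rem <- which(st == "REM")
  rms_ep[i_rem] <- rms_ep[i_rem] *
    exp(rnorm(length(i_rem), 0, params$emg_rem_twitch_sd))
  emg <- rnorm(n_ep * N) * rep(rms_ep, each = N)

  structure(list(eeg = eeg, emg = unname(emg), fs = fs,
                 epoch_len = EPOCH_SEC, seed = as.integer(seed)),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", length(x$eeg) / x$fs / 3600, " h at ", x$fs,
      " Hz (EEG + EMG)\n", sep = "")
  invisible(x)
}

#' EMG root-mean-square per epoch
#'
#' @param rec A `psg_recording`.
#' @return Numeric vector: RMS of the EMG channel in each 4-s epoch, uV.
#' @export
emg_epoch_rms <- function(rec) {
  N <- rec$epoch_len * rec$fs
  n_ep <- length(rec$emg) %/% N
  sqrt(colMeans(matrix(rec$emg[seq_len(n_ep * N)]^2, N, n_ep)))
}
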