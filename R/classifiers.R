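#' Classify theta-dominated wakefulness (TDW)
#'
#' A WAKE epoch is theta-dominated when the maximum of its power spectrum
#' over 0.75-12 Hz falls inside the 6.0-9.5 Hz theta band. Non-wake epochs
#' are never TDW (the state gate): cataplexy is theta-dominated too but is
#' its own state.
#'
#' @param spec An [epoch_spectra()] object.
#' @param hyp The matching [hypnogram()].
#' @param theta_band Numeric length-2: TDW band in Hz (default 6.0-9.5).
#' @param search Numeric length-2: dominance search range (default
#'   0.75-12 Hz, the range in which wake EEG peaks are sought).
#' @return Logical vector, one flag per epoch (`FALSE` for non-WAKE).
#' @export
classify_tdw <- function(spec, hyp, theta_band = c(6, 9.5),
                         search = c(0.75, 12)) {
  if (nrow(spec$power) != nrow(hyp))
    stop("spectra and hypnogram disagree on epoch count")
  sel <- which(spec$freq >= search[1] & spec$freq <= search[2])
  sub <- spec$power[, sel, drop = FALSE]
  peak_f <- spec$freq[sel[max.col(sub, ties.method = "first")]]
  as_state_chr(hyp) == "WAKE" & peak_f >= theta_band[1] & peak_f <= theta_band[2]
}

#' Detect cataplexy episodes from EEG/EMG
#'
#' Operational murine cataplexy detection: an episode is a maximal run of
#' at least `min_duration` seconds of epochs that are (i) scored as
#' wakefulness, (ii) atonic (EMG RMS below threshold), (iii)
#' theta-dominated ([classify_tdw()] criterion), and (iv) directly
#' preceded by at least `min_wake_before` seconds of wakefulness with
#' supra-threshold EMG. The atonia threshold is self-calibrating:
#' `mean + 2 SD` of the per-epoch EMG RMS over the recording's REM epochs.
#' Runs interrupted by even a single non-qualifying epoch are split (no
#' smoothing).
#'
#' By default, epochs scored `CATAPLEXY` are treated as wakefulness
#' (validation mode: detection re-discovers episodes that scoring already
#' labelled). Set `use_cataplexy_label = FALSE` when the hypnogram was
#' scored without a cataplexy class.
#'
#' @param rec A `psg_recording` (the EMG channel is required).
#' @param hyp The matching [hypnogram()].
#' @param spec Optional precomputed [epoch_spectra()]; computed from `rec`
#'   if missing.
#' @param min_duration Minimum episode length, seconds (default 12 = 3
#'   epochs).
#' @param min_wake_before Required prior active wakefulness, seconds
#'   (default 40 = 10 epochs).
#' @param atonia_threshold Override the self-calibrated threshold (uV).
#' @param use_cataplexy_label Treat `CATAPLEXY`-scored epochs as wake
#'   candidates (default `TRUE`).
#' @return data.frame of episodes: `start_epoch` (1-based), `n_epochs`,
#'   `duration` (s), `preceding_wake` (s), `zt_start` (hours).
#' @export
detect_cataplexy <- function(rec, hyp, spec = NULL,
                             min_duration = 12, min_wake_before = 40,
                             atonia_threshold = NULL,
                             use_cataplexy_label = TRUE) {
  if (is.null(rec$emg) || !length(rec$emg)) stop("EMG channel missing")
  if (is.null(spec)) spec <- epoch_spectra(rec)
  st <- as_state_chr(hyp)
  rms <- emg_epoch_rms(rec)
  if (length(rms) != length(st))
    stop("recording and hypnogram disagree on epoch count")
  if (is.null(atonia_threshold)) {
    rem_rms <- rms[st == "REM"]
    if (!length(rem_rms))
      stop("no REM epochs to calibrate the atonia threshold; supply atonia_threshold")
    atonia_threshold <- mean(rem_rms) + 2 * sd(rem_rms)
    if (is.na(atonia_threshold)) atonia_threshold <- mean(rem_rms) * 1.5
  }
  wakeish <- st == "WAKE" | (use_cataplexy_label & st == "CATAPLEXY")
  # theta dominance on a wake-relabelled copy so the state gate passes
  hyp2 <- hyp
  hyp2$state[wakeish] <- "WAKE"
  tdw <- classify_tdw(spec, hyp2)
  atonic <- rms < atonia_threshold
  candidate <- wakeish & atonic & tdw
  active_wake <- wakeish & !atonic

  min_ep <- ceiling(min_duration / EPOCH_SEC)
  need_wake <- ceiling(min_wake_before / EPOCH_SEC)
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in which(r$values & r$lengths >= min_ep)) {
    s0 <- starts[j]
    # count contiguous active-wake epochs immediately before the run
    k <- s0 - 1L
    prior <- 0L
    while (k >= 1L && active_wake[k]) { prior <- prior + 1L; k <- k - 1L }
    if (prior >= need_wake) {
      out[[length(out) + 1L]] <- data.frame(
        start_epoch = s0, n_epochs = r$lengths[j],
        duration = r$lengths[j] * EPOCH_SEC,
        preceding_wake = prior * EPOCH_SEC,
        zt_start = zt_hours(hyp)[s0])
    }
  }
  if (!length(out))
    return(data.frame(start_epoch = integer(), n_epochs = integer(),
                      duration = numeric(), preceding_wake = numeric(),
                      zt_start = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
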