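#' Canonical EEG frequency bands
#'
#' The band set used throughout rodent sleep-EEG work: delta 1-4 Hz,
#' slow-delta variants (1-2, 0.75-2.5, 0.75-1 Hz), fast-delta 3-4 Hz,
#' REM theta 6.5-8.5 Hz, the theta-peak search range 6-8 Hz, the
#' theta-dominated-wakefulness band 6.0-9.5 Hz, slow-gamma 32-45 Hz,
#' fast-gamma 55-80 Hz and the 0.75-47.5 Hz normalization reference range.
#' Band edges are inclusive at both ends: [band_power()] sums every bin
#' with `lo <= f <= hi`.
#'
#' @param name Optional single band name.
#' @return A `band` object, or the full named list of them.
#' @export
eeg_bands <- function(name = NULL) {
  b <- list(
    delta = band("delta", 1, 4),
    slow_delta = band("slow_delta", 1, 2),
    fast_delta = band("fast_delta", 3, 4),
    waking_slow_delta = band("waking_slow_delta", 0.75, 2.5),
    slowest_delta = band("slowest_delta", 0.75, 1),
    theta = band("theta", 6.5, 8.5),
    theta_peak = band("theta_peak", 6, 8),
    tdw = band("tdw", 6, 9.5),
    slow_gamma = band("slow_gamma", 32, 45),
    fast_gamma = band("fast_gamma", 55, 80),
    reference = band("reference", 0.75, 47.5)
  )
  if (is.null(name)) return(b)
  if (!name %in% names(b)) stop("unknown band: ", name)
  b[[name]]
}

#' Construct a frequency band
#' @param name Band label.
#' @param lo,hi Band edges in Hz, inclusive, multiples of 0.25 within 0-90.
#' @return A `band` object (list with `name`, `lo`, `hi`).
#' @export
band <- function(name, lo, hi) {
  if (lo < 0 || hi > 90 || lo > hi)
    stop("band must satisfy 0 <= lo <= hi <= 90")
  if (any(abs(c(lo, hi) / 0.25 - round(c(lo, hi) / 0.25)) > 1e-9))
    stop("band edges must be multiples of 0.25 Hz")
  structure(list(name = name, lo = lo, hi = hi), class = "band")
}

#' Per-epoch EEG power spectra
#'
#' Applies a rectangular-window discrete Fourier transform to each 4-s
#' epoch of the EEG channel and returns one-sided power per frequency bin,
#' 0-90 Hz at the native 0.25 Hz resolution (361 bins). Power is scaled so
#' that, when the spectrum extends to the Nyquist frequency, the sum over
#' bins equals the epoch mean square (Parseval): a bin-aligned sinusoid of
#' amplitude `a` contributes `a^2/2` in exactly one bin.
#'
#' @param rec A `psg_recording` (or any list with `eeg`, `fs`,
#'   `epoch_len`).
#' @param taper Optional taper: `"none"` (default, matching the direct
#'   per-epoch DFT convention) or `"hanning"`.
#' @return Object of class `epoch_spectra`: list with `power`
#'   (epochs x 361 matrix, uV^2), `freq` (Hz) and `fs`.
#' @export
epoch_spectra <- function(rec, taper = c("none", "hanning")) {
  taper <- match.arg(taper)
  fs <- rec$fs
  if (fs < 180) stop("fs must be >= 180 Hz to reach 90 Hz")
  N <- rec$epoch_len * fs
  n_total <- length(rec$eeg)
  if (n_total %% N != 0)
    stop("sample count is not a whole number of 4-s epochs")
  n_ep <- n_total %/% N
  nb <- 361L  # 0..90 Hz step 0.25
  win <- if (taper == "hanning") 0.5 - 0.5 * cos(2 * pi * seq_len(N) / (N + 1)) else rep(1, N)
  wnorm <- sum(win^2) / N
  onesided <- c(1, rep(2, nb - 1L))
  if ((nb - 1L) == N %/% 2L) onesided[nb] <- 1  # 90 Hz is Nyquist when fs = 180

  power <- matrix(0, n_ep, nb)
  chunk <- 4096L
  for (j0 in seq(1L, n_ep, by = chunk)) {
    j1 <- min(j0 + chunk - 1L, n_ep)
    x <- matrix(rec$eeg[((j0 - 1L) * N + 1L):(j1 * N)], N, j1 - j0 + 1L) * win
    f <- mvfft(x)[seq_len(nb), , drop = FALSE]
    power[j0:j1, ] <- t(Mod(f)^2 * (onesided / (N^2 * wnorm)))
  }
  structure(list(power = power, freq = seq(0, 90, by = 0.25), fs = fs),
            class = "epoch_spectra")
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat("<epoch_spectra> ", nrow(x$power), " epochs x ", ncol(x$power),
      " bins (0-90 Hz @ 0.25 Hz)\n", sep = "")
  invisible(x)
}

#' Artifact-free, same-state-flanked epoch selection
#'
#' An epoch enters spectral averages only if it and both neighbours exist,
#' share the given state and are artifact-free — the standard guard
#' against state-transition and artifact contamination of sleep spectra.
#'
#' @param hyp A [hypnogram()].
#' @param state State label (`WAKE`, `NREM`, `REM`, `CATAPLEXY`).
#' @return Integer vector of selected (1-based) epoch indices.
#' @export
select_scorable_epochs <- function(hyp, state) {
  state <- match.arg(state, STATES)
  ok <- (as_state_chr(hyp) == state) & !hyp$artifact
  n <- length(ok)
  if (n < 3L) return(integer(0))
  mid <- 2:(n - 1L)
  mid[ok[mid] & ok[mid - 1L] & ok[mid + 1L]]
}

#' Mean spectrum over selected epochs
#'
#' @param spec An [epoch_spectra()] object.
#' @param indices Epoch indices (1-based), e.g. from
#'   [select_scorable_epochs()].
#' @return Numeric 361-bin spectrum, or all-`NA` (with a warning) when
#'   `indices` is empty — an absent state in an interval is undefined,
#'   not zero.
#' @export
state_mean_spectrum <- function(spec, indices) {
  if (length(indices) == 0) {
    warning("no epochs selected; state absent in interval")
    return(rep(NA_real_, ncol(spec$power)))
  }
  colMeans(spec$power[indices, , drop = FALSE])
}

#' State-weighted baseline power reference
#'
#' The per-mouse normalization denominator: total 0.75-47.5 Hz EEG power
#' on baseline day one, averaged within each vigilance state over its
#' scorable (artifact-free, same-state-flanked) epochs and then combined
#' across WAKE/NREM/REM with *fixed cohort-level weights*, so that the
#' relative contribution of each state to the reference is identical for
#' every mouse regardless of its own state amounts.
#'
#' @param spec An [epoch_spectra()] object.
#' @param hyp The matching [hypnogram()].
#' @param weights Named numeric over WAKE/NREM/REM summing to 1. Supply
#'   the cohort mean scorable-epoch state fractions
#'   ([cohort_state_weights()]); `NULL` uses this mouse's own fractions.
#' @param day Baseline day used (default 1).
#' @return List of class `norm_reference`: `value` (uV^2), `state_weights`,
#'   and `per_state_power`.
#' @export
baseline_reference <- function(spec, hyp, weights = NULL, day = 1L) {
  ref_band <- eeg_bands("reference")
  sel_band <- spec$freq >= ref_band$lo & spec$freq <= ref_band$hi
  in_day <- day_of(hyp) == day
  if (!any(in_day)) stop("baseline day ", day, " not present in recording")
  states3 <- c("WAKE", "NREM", "REM")
  per_state <- numeric(3); names(per_state) <- states3
  n_scorable <- integer(3); names(n_scorable) <- states3
  for (s in states3) {
    idx <- select_scorable_epochs(hyp, s)
    idx <- idx[in_day[idx]]
    if (length(idx) == 0)
      stop("no scorable ", s, " epochs on baseline day ", day)
    per_state[s] <- mean(rowSums(spec$power[idx, sel_band, drop = FALSE]))
    n_scorable[s] <- length(idx)
  }
  if (is.null(weights)) weights <- n_scorable / sum(n_scorable)
  if (!all(states3 %in% names(weights)))
    stop("weights must name WAKE, NREM and REM")
  weights <- weights[states3]
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  structure(list(value = sum(weights * per_state),
                 state_weights = weights,
                 per_state_power = per_state),
            class = "norm_reference")
}

#' Cohort-level state weights for the baseline reference
#'
#' @param hyps List of [hypnogram()]s (one per mouse).
#' @param day Baseline day (default 1).
#' @return Named numeric: mean scorable-epoch state fractions across the
#'   cohort, summing to 1 over WAKE/NREM/REM.
#' @export
cohort_state_weights <- function(hyps, day = 1L) {
  states3 <- c("WAKE", "NREM", "REM")
  fr <- sapply(hyps, function(h) {
    in_day <- day_of(h) == day
    n <- vapply(states3, function(s) {
      idx <- select_scorable_epochs(h, s)
      sum(in_day[idx])
    }, numeric(1))
    n / sum(n)
  })
  w <- rowMeans(fr)
  w / sum(w)
}

#' Normalize a spectrum to a baseline reference
#'
#' @param spectrum Numeric spectrum (uV^2 per bin).
#' @param ref A `norm_reference` from [baseline_reference()], or a single
#'   positive number.
#' @return The spectrum expressed in percent of the reference value.
#' @export
normalize_spectrum <- function(spectrum, ref) {
  value <- if (inherits(ref, "norm_reference")) ref$value else ref
  if (!is.finite(value) || value <= 0) stop("reference value must be > 0")
  spectrum * 100 / value
}

#' Band power of a spectrum
#'
#' Sums the bins with `lo <= f <= hi`, inclusive at both edges (so bands
#' sharing an edge double-count exactly the shared bin).
#'
#' @param spectrum Numeric 361-bin spectrum, or a matrix with 361 columns
#'   (rows are epochs).
#' @param bd A [band()].
#' @return Scalar band power, or one value per row for a matrix.
#' @export
band_power <- function(spectrum, bd) {
  stopifnot(inherits(bd, "band"))
  freq <- seq(0, 90, by = 0.25)
  sel <- freq >= bd$lo & freq <= bd$hi
  if (is.matrix(spectrum)) {
    if (ncol(spectrum) != length(freq)) stop("expected 361 frequency bins")
    return(rowSums(spectrum[, sel, drop = FALSE]))
  }
  if (length(spectrum) != length(freq)) stop("expected 361 frequency bins")
  sum(spectrum[sel])
}

#' Theta peak frequency (TPF)
#'
#' Frequency of the maximum bin of a (REM) mean spectrum within the search
#' band. The default 5-10 Hz window is wider than the conventional 6-8 Hz
#' theta-peak range so that fast peaks (e.g. 8.25 Hz) are still found.
#' Ties break toward the lower frequency.
#'
#' @param spectrum Numeric 361-bin spectrum.
#' @param search Numeric length-2: search band in Hz.
#' @return Peak frequency in Hz (0.25 Hz resolution).
#' @export
theta_peak_frequency <- function(spectrum, search = c(5, 10)) {
  freq <- seq(0, 90, by = 0.25)
  sel <- which(freq >= search[1] & freq <= search[2])
  vals <- spectrum[sel]
  if (all(!is.finite(vals))) return(NA_real_)
  if (diff(range(vals)) == 0)
    warning("flat spectrum in the search band; returning its lower edge")
  freq[sel[which.max(vals)]]
}
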