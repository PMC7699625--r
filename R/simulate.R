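#' Simulate a scored mouse hypnogram
#'
#' Semi-Markov generation of vigilance states on the 4-s epoch grid. WAKE
#' and NREM alternate; REM is entered only from NREM (with probability
#' `p_rem_entry`) and exits to WAKE or NREM; cataplexy is entered only from
#' WAKE — and only after at least 40 s (10 epochs) of continuous prior
#' wakefulness — at `cataplexy_rate` episodes per hour of wakefulness, and
#' exits to WAKE. Dwell times are geometric in epochs with the preset's
#' mean, which makes the per-epoch formulation below exact: each epoch the
#' current state is left with probability `1/mean_epochs`. Rates switch
#' between their light and dark values at ZT0/ZT12. Cataplexy episodes have
#' a 12-s (3-epoch) minimum duration. Each WAKE epoch is independently
#' flagged as theta-dominated (TDW) with probability `tdw_prob[phase]`;
#' the flag selects which oscillator [synthesize_signals()] plants.
#'
#' @param params A [genotype_params()] preset.
#' @param days Number of 24-h recording days (recording starts at ZT0).
#' @param seed Integer seed; identical `(params, days, seed)` give
#'   bitwise-identical hypnograms.
#' @param init_state State occupied at the first epoch.
#' @return A [hypnogram()] with a `tdw` column of ground-truth flags.
#' @examples
#' h <- simulate_hypnogram(genotype_presets("WT"), days = 1, seed = 1)
#' table(h$state)
#' @export
simulate_hypnogram <- function(params, days, seed, init_state = "WAKE") {
  stopifnot(inherits(params, "genotype_params"))
  if (days < 1) stop("days must be >= 1")
  n <- as.integer(days) * EPOCHS_PER_DAY
  set.seed(as.integer(seed))

  light <- (((seq_len(n) - 1) * EPOCH_SEC / 3600) %% 24) < 12
  u_cat <- runif(n); u_leave <- runif(n); u_branch <- runif(n); u_tdw <- runif(n)

  # mean dwell in epochs, per state x phase
  m <- vapply(c("light", "dark"), function(ph)
    params$dwell_mean[[ph]][c("WAKE", "NREM", "REM")] / EPOCH_SEC,
    numeric(3))  # 3 x 2 matrix, rows WAKE/NREM/REM
  m_cat <- params$cataplexy_dwell_mean / EPOCH_SEC
  p_cat_epoch <- params$cataplexy_rate * EPOCH_SEC / 3600  # per wake epoch
  # leave probability after the 3-epoch minimum so total mean stays m_cat
  p_cat_leave <- 1 / max(m_cat - 2, 1)

  states <- integer(n)  # 1=WAKE 2=NREM 3=REM 4=CATAPLEXY
  tdw <- logical(n)
  s <- match(init_state, STATES)
  if (is.na(s)) stop("unknown init_state")
  run <- 0L
  for (i in seq_len(n)) {
    states[i] <- s
    run <- run + 1L
    ph <- if (light[i]) 1L else 2L
    if (s == 1L) {
      tdw[i] <- u_tdw[i] < params$tdw_prob[[ph]]
      if (run >= 10L && u_cat[i] < p_cat_epoch[[ph]]) {
        s <- 4L; run <- 0L
      } else if (u_leave[i] < 1 / m[1L, ph]) {
        s <- 2L; run <- 0L
      }
    } else if (s == 2L) {
      if (u_leave[i] < 1 / m[2L, ph]) {
        s <- if (u_branch[i] < params$p_rem_entry[[ph]]) 3L else 1L
        run <- 0L
      }
    } else if (s == 3L) {
      if (u_leave[i] < 1 / m[3L, ph]) {
        s <- if (u_branch[i] < params$p_rem_exit_wake[[ph]]) 1L else 2L
        run <- 0L
      }
    } else {
      if (run >= 3L && u_leave[i] < p_cat_leave) {
        s <- 1L; run <- 0L
      }
    }
  }
  hypnogram(STATES[states], artifact = FALSE, tdw = tdw, zt0_index = 1L)
}

#' Enforce a sleep-deprivation window
#'
#' Overwrites every epoch of the given day whose Zeitgeber time falls in
#' `[start_zt, start_zt + duration)` with WAKE, leaving all other epochs
#' unchanged. Converted epochs are flagged TDW: enforced wakefulness in
#' mice is active, theta-dominated waking. Epochs already scored WAKE keep
#' their original TDW flag.
#'
#' @param hyp A [hypnogram()].
#' @param day 1-based recording day to deprive.
#' @param start_zt Window start, ZT hours (default 0 = lights-on).
#' @param duration Window length in hours (default 6).
#' @return The modified hypnogram.
#' @export
apply_sleep_deprivation <- function(hyp, day, start_zt = 0, duration = 6) {
  if (duration == 0) return(hyp)
  if (duration < 0) stop("duration must be >= 0")
  zt <- zt_hours(hyp)
  d <- day_of(hyp)
  idx <- which(d == day & zt >= start_zt & zt < start_zt + duration)
  expected <- duration * 3600 / EPOCH_SEC
  if (length(idx) < expected)
    stop("sleep-deprivation window extends outside the recording")
  was_wake <- hyp$state[idx] == "WAKE"
  hyp$state[idx] <- "WAKE"
  if (!is.null(hyp$tdw)) hyp$tdw[idx[!was_wake]] <- TRUE
  hyp
}

#' Process-S (homeostatic sleep pressure) trajectory
#'
#' Classic two-process recursion evaluated per 4-s epoch: during WAKE, REM
#' and cataplexy S rises towards 1 as
#' `S <- 1 - (1 - S) * exp(-dt / tau_rise)`; during NREM it decays towards
#' 0 as `S <- S * exp(-dt / tau_decay)`. The returned value is S at the
#' *end* of each epoch, so the trajectory is bounded in `[0, 1]` and
#' piecewise monotone over every same-state run.
#'
#' @param hyp A [hypnogram()].
#' @param tau_rise,tau_decay Time constants in hours.
#' @param s0 Initial value of S.
#' @return Numeric vector, one S value per epoch.
#' @export
process_s <- function(hyp, tau_rise = 8, tau_decay = 2, s0 = 0.5) {
  if (tau_rise <= 0 || tau_decay <= 0) stop("time constants must be positive")
  st <- as_state_chr(hyp)
  rising <- st != "NREM"
  dt <- EPOCH_SEC / 3600
  s <- numeric(length(st))
  r <- rle(rising)
  pos <- 1L
  cur <- s0
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[j]
    k <- seq_len(len)
    if (r$values[j]) {
      seg <- 1 - (1 - cur) * exp(-k * dt / tau_rise)
    } else {
      seg <- cur * exp(-k * dt / tau_decay)
    }
    s[pos:(pos + len - 1L)] <- seg
    cur <- seg[len]
    pos <- pos + len
  }
  s
}

#' Flag a random fraction of epochs as artifacts
#'
#' @param hyp A [hypnogram()].
#' @param fraction Proportion of epochs to flag, in `[0, 1)`; the flagged
#'   count is `round(fraction * n_epochs)`.
#' @param seed Integer seed (sampling is uniform without replacement).
#' @return The hypnogram with updated `artifact` flags; states unchanged.
#' @export
mark_artifacts <- function(hyp, fraction, seed) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  n <- nrow(hyp)
  k <- round(fraction * n)
  if (k > 0) {
    set.seed(as.integer(seed))
    hyp$artifact[sample.int(n, k)] <- TRUE
  }
  hyp
}

#' Stationary state occupancy of the semi-Markov chain
#'
#' Analytic long-run fractions of time in WAKE, NREM and REM for one light
#' phase, from the embedded three-state jump chain: with WAKE always ending
#' into NREM, NREM ending into REM with probability `p` (else WAKE) and REM
#' ending into WAKE with probability `q` (else NREM), the embedded-chain
#' stationary weights are proportional to `(1 - p + p*q, 1, p)`; occupancy
#' is those weights times the mean dwell times, renormalized. Cataplexy is
#' ignored (set `cataplexy_rate = 0` when comparing to simulation).
#'
#' @param params A [genotype_params()].
#' @param phase `"light"` or `"dark"`.
#' @return Named numeric: long-run fraction of time in WAKE/NREM/REM.
#' @export
stationary_occupancy <- function(params, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  p <- params$p_rem_entry[[phase]]
  q <- params$p_rem_exit_wake[[phase]]
  pi_embed <- c(WAKE = 1 - p + p * q, NREM = 1, REM = p)
  m <- params$dwell_mean[[phase]][c("WAKE", "NREM", "REM")]
  occ <- pi_embed * m
  occ / sum(occ)
}
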