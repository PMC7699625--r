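#' Percentile scheme for band-power time-courses
#'
#' Number of percentiles allocated per state and recording interval. Sleep
#' states get 12 percentiles per baseline light period, 6 per dark period
#' and 8 for the 6-h light period after sleep deprivation (SD); wakefulness
#' gets 6 (light), 12 (dark), 8 (during the 6-h SD) and 4 (6-h light after
#' SD). NREM and REM have no SD entry because enforced wakefulness leaves
#' them no epochs there. Recovery-dark periods reuse the dark counts.
#'
#' @return Named list (`WAKE`, `NREM`, `REM`) of named numerics over
#'   intervals `baseline_light`, `baseline_dark`, `sd`, `recovery_light`,
#'   `recovery_dark`.
#' @export
percentile_scheme <- function() {
  sleep <- c(baseline_light = 12, baseline_dark = 6, sd = NA,
             recovery_light = 8, recovery_dark = 6)
  list(
    WAKE = c(baseline_light = 6, baseline_dark = 12, sd = 8,
             recovery_light = 4, recovery_dark = 12),
    NREM = sleep,
    REM = sleep
  )
}

#' Partition ordered epochs into percentiles
#'
#' Splits a chronologically ordered index vector into `n` contiguous
#' groups whose sizes differ by at most one, remainder epochs going to the
#' earliest groups; concatenating the groups reproduces the input.
#'
#' @param indices Ordered epoch indices.
#' @param n Number of groups.
#' @return List of `n` index vectors.
#' @export
partition_percentiles <- function(indices, n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  len <- length(indices)
  if (len < n) stop("fewer epochs (", len, ") than percentiles (", n, ")")
  sizes <- rep(len %/% n, n)
  extra <- len %% n
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n] + 1L)
  lapply(seq_len(n), function(k) indices[starts[k]:ends[k]])
}

# Internal: interval table for a recording with optional SD day.
# Baseline days are the days before sd_day (all days when sd_day is NULL).
protocol_intervals <- function(days, sd_day = NULL) {
  rows <- list()
  for (d in seq_len(days)) {
    if (!is.null(sd_day) && d == sd_day) {
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, kind = c("sd", "recovery_light", "recovery_dark"),
        zt_from = c(0, 6, 12), zt_to = c(6, 12, 24))
    } else {
      kind <- if (!is.null(sd_day) && d > sd_day) c("post_light", "post_dark")
              else c("baseline_light", "baseline_dark")
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, kind = kind, zt_from = c(0, 12), zt_to = c(12, 24))
    }
  }
  do.call(rbind, rows)
}

#' Percentile band-power time-course
#'
#' The dynamics of one frequency band in one vigilance state across the
#' recording. Within each interval (baseline light/dark per day, the SD
#' window, recovery light and dark), the state's scorable epochs
#' (artifact-free, same-state-flanked; see [select_scorable_epochs()]) are
#' split into the scheme's number of equal-occupancy percentiles; the band
#' power is averaged within each percentile and normalized to percent of
#' either (mode `"state_baseline"`) the state's mean band power over both
#' baseline days, or (mode `"zt8_12_delta"`, the NREM-delta convention)
#' the mean NREM delta power in ZT8-12 of the baseline days.
#'
#' @param spec An [epoch_spectra()] object.
#' @param hyp The matching [hypnogram()].
#' @param state `WAKE`, `NREM` or `REM`.
#' @param bd A [band()].
#' @param scheme A [percentile_scheme()].
#' @param mode Normalization mode (see above).
#' @param sd_day 1-based day of the 6-h ZT0-6 sleep deprivation, or `NULL`.
#' @return data.frame: `interval`, `day`, `percentile`, `n_epochs`,
#'   `zt_center` (cumulative hours from recording start) and
#'   `value_percent`. Intervals with too few epochs yield `NA` values.
#' @export
band_power_timecourse <- function(spec, hyp, state, bd,
                                  scheme = percentile_scheme(),
                                  mode = c("state_baseline", "zt8_12_delta"),
                                  sd_day = NULL) {
  mode <- match.arg(mode)
  state <- match.arg(state, c("WAKE", "NREM", "REM"))
  stopifnot(inherits(bd, "band"))
  days <- nrow(hyp) %/% EPOCHS_PER_DAY
  scorable <- select_scorable_epochs(hyp, state)
  bp_all <- band_power(spec$power, bd)  # per-epoch band power
  zt_cum <- (seq_len(nrow(hyp)) - 1) * EPOCH_SEC / 3600  # hours from start

  baseline_days <- if (is.null(sd_day)) seq_len(days) else seq_len(sd_day - 1L)
  if (length(baseline_days) == 0) stop("no baseline day before sd_day")
  denom <- if (mode == "state_baseline") {
    idx <- scorable[day_of(hyp)[scorable] %in% baseline_days]
    if (length(idx) == 0) stop("no scorable baseline epochs for ", state)
    mean(bp_all[idx])
  } else {
    nidx <- select_scorable_epochs(hyp, "NREM")
    nidx <- nidx[day_of(hyp)[nidx] %in% baseline_days &
                   zt_hours(hyp)[nidx] >= 8 & zt_hours(hyp)[nidx] < 12]
    if (length(nidx) == 0) stop("no scorable baseline ZT8-12 NREM epochs")
    mean(band_power(spec$power[nidx, , drop = FALSE], eeg_bands("delta")))
  }

  iv <- protocol_intervals(days, sd_day)
  zt <- zt_hours(hyp); dd <- day_of(hyp)
  counts <- scheme[[state]]
  out <- list()
  for (r in seq_len(nrow(iv))) {
    kind <- iv$kind[r]
    key <- sub("^post_", "baseline_", kind)
    n_pct <- counts[[key]]
    if (is.na(n_pct)) next  # state undefined in this interval (e.g. sleep in SD)
    idx <- scorable[dd[scorable] == iv$day[r] &
                      zt[scorable] >= iv$zt_from[r] & zt[scorable] < iv$zt_to[r]]
    if (length(idx) < n_pct) {
      out[[length(out) + 1L]] <- data.frame(
        interval = kind, day = iv$day[r], percentile = seq_len(n_pct),
        n_epochs = 0L, zt_center = NA_real_, value_percent = NA_real_)
      next
    }
    groups <- partition_percentiles(idx, n_pct)
    out[[length(out) + 1L]] <- data.frame(
      interval = kind, day = iv$day[r], percentile = seq_along(groups),
      n_epochs = lengths(groups),
      zt_center = vapply(groups, function(gi) mean(zt_cum[gi]), numeric(1)),
      value_percent = vapply(groups, function(gi) 100 * mean(bp_all[gi]) / denom,
                             numeric(1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average a time-course across baseline days
#'
#' Collapses the `baseline_light`/`baseline_dark` rows of a
#' [band_power_timecourse()] result over days, percentile by percentile,
#' as is done when plotting "baselines averaged". Non-baseline rows pass
#' through unchanged.
#'
#' @param tc data.frame from [band_power_timecourse()].
#' @return data.frame of the same shape, with a single averaged baseline
#'   day (`day = NA`).
#' @export
average_baselines <- function(tc) {
  is_bl <- tc$interval %in% c("baseline_light", "baseline_dark")
  if (!any(is_bl)) return(tc)
  bl <- tc[is_bl, , drop = FALSE]
  agg <- aggregate(cbind(value_percent, n_epochs) ~ interval + percentile,
                   data = bl, FUN = mean, na.action = stats::na.pass)
  # keep day-1 zt positions so the averaged curve plots on the first day
  zt1 <- bl[bl$day == min(bl$day), c("interval", "percentile", "zt_center")]
  agg <- merge(agg, zt1, by = c("interval", "percentile"), sort = FALSE)
  agg$day <- NA_integer_
  agg <- agg[order(match(agg$interval, unique(tc$interval)), agg$percentile),
             c("interval", "day", "percentile", "n_epochs", "zt_center",
               "value_percent")]
  out <- rbind(agg, tc[!is_bl, , drop = FALSE])
  rownames(out) <- NULL
  out
}
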