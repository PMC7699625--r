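#' Detect vigilance-state bouts
#'
#' A bout is a maximal run of consecutive same-state epochs. The bouts of
#' all states tile the hypnogram exactly; artifact epochs keep their state
#' (artifacts matter only for spectral analysis). Cataplexy is its own
#' state, so cataplexy epochs never extend WAKE bouts.
#'
#' @param hyp A [hypnogram()].
#' @param state Optional state label to filter on (`WAKE`, `NREM`, `REM`,
#'   `CATAPLEXY`); `NULL` returns bouts of all states in order.
#' @return data.frame with columns `state`, `start_epoch` (1-based),
#'   `n_epochs`, `duration` (seconds).
#' @examples
#' detect_bouts(hypnogram(c("N", "N", "R", "R", "R", "W")))
#' @export
detect_bouts <- function(hyp, state = NULL) {
  if (!is.null(state)) state <- match.arg(state, STATES)
  st <- as_state_chr(hyp)
  if (length(st) == 0) {
    out <- data.frame(state = character(), start_epoch = integer(),
                      n_epochs = integer(), duration = numeric())
    return(out)
  }
  r <- rle(st)
  out <- data.frame(
    state = r$values,
    start_epoch = cumsum(c(1L, r$lengths[-length(r$lengths)])),
    n_epochs = r$lengths,
    duration = r$lengths * EPOCH_SEC
  )
  if (!is.null(state)) out <- out[out$state == state, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bout-duration histogram
#'
#' Bins bout durations into left-closed, right-open classes labelled by
#' their lower edge (the convention of bout-distribution figures, whose x
#' axes list lower bin bounds); the last bin is open-ended. Bouts shorter
#' than the first edge are returned separately as `sub_threshold`.
#'
#' @param bouts data.frame from [detect_bouts()], or a numeric vector of
#'   durations in seconds.
#' @param bin_lowers Strictly increasing lower bin edges, seconds.
#' @return List: `counts` (named integer per bin) and `sub_threshold`.
#' @export
bout_duration_histogram <- function(bouts, bin_lowers = c(8, 16, 32, 64, 128, 256)) {
  if (is.unsorted(bin_lowers, strictly = TRUE))
    stop("bin_lowers must be strictly increasing")
  dur <- if (is.data.frame(bouts)) bouts$duration else as.numeric(bouts)
  cuts <- c(bin_lowers, Inf)
  counts <- vapply(seq_along(bin_lowers), function(k)
    sum(dur >= cuts[k] & dur < cuts[k + 1]), integer(1))
  names(counts) <- as.character(bin_lowers)
  list(counts = counts, sub_threshold = sum(dur < bin_lowers[1]))
}

#' Count long REM-sleep bouts
#'
#' @param bouts data.frame of REM bouts (or numeric durations, seconds).
#' @param threshold Duration threshold in seconds (default 120 = 2 min);
#'   the comparison is strict (`duration > threshold`).
#' @return Integer count.
#' @export
long_rem_bout_count <- function(bouts, threshold = 120) {
  dur <- if (is.data.frame(bouts)) bouts$duration else as.numeric(bouts)
  sum(dur > threshold)
}

#' State time-course in minutes per hour
#'
#' Minutes spent in a state per hour of recording, averaged over
#' non-overlapping windows (default 2 h, the usual plotting resolution).
#' `state = "TDW"` counts the theta-dominated WAKE epochs instead (the
#' hypnogram must carry a `tdw` column).
#'
#' @param hyp A [hypnogram()] spanning whole hours.
#' @param state State label, or `"TDW"`.
#' @param window_hours Averaging window in hours; must divide the number
#'   of recorded hours.
#' @param average_days Fold the time-course across 24-h days and average
#'   (used to average baseline days); requires whole days.
#' @return data.frame with `zt_center` (hours from recording start, or
#'   within 0-24 when `average_days`) and `minutes_per_hour`.
#' @export
state_time_course <- function(hyp, state, window_hours = 2, average_days = FALSE) {
  n <- nrow(hyp)
  per_h <- 3600 / EPOCH_SEC
  if (n %% per_h != 0) stop("hypnogram must span whole hours")
  hours <- n %/% per_h
  in_state <- if (identical(state, "TDW")) {
    if (is.null(hyp$tdw)) stop("hypnogram has no tdw column")
    hyp$tdw & as_state_chr(hyp) == "WAKE"
  } else {
    as_state_chr(hyp) == match.arg(state, STATES)
  }
  mph <- colSums(matrix(in_state, per_h, hours)) * EPOCH_SEC / 60
  if (average_days) {
    if (hours %% 24 != 0) stop("average_days requires whole days")
    mph <- rowMeans(matrix(mph, 24, hours %/% 24))
    hours <- 24
  }
  if (hours %% window_hours != 0)
    stop("window_hours must divide the recorded hours")
  nw <- hours %/% window_hours
  win_mean <- colMeans(matrix(mph, window_hours, nw))
  data.frame(
    zt_center = (seq_len(nw) - 0.5) * window_hours,
    minutes_per_hour = win_mean
  )
}

#' Epoch indices of a Zeitgeber window
#'
#' @param hyp A [hypnogram()].
#' @param day 1-based recording day, or `NULL` for all days.
#' @param zt_from,zt_to Half-open ZT window `[zt_from, zt_to)` in hours.
#' @return Integer vector of 1-based epoch indices.
#' @export
epochs_in <- function(hyp, day = NULL, zt_from = 0, zt_to = 24) {
  zt <- zt_hours(hyp)
  keep <- zt >= zt_from & zt < zt_to
  if (!is.null(day)) keep <- keep & day_of(hyp) %in% day
  which(keep)
}

#' REM-sleep latency
#'
#' Latency from sleep onset to REM sleep, within a period of the
#' recording. Sleep onset is the first consolidated NREM bout: a maximal
#' run of at least three consecutive NREM epochs whose immediately
#' preceding non-NREM run contains at least one WAKE epoch (cataplexy does
#' not qualify). The event ends at the first subsequent run of at least
#' two consecutive REM epochs; latency is 4 s times the index difference
#' between the first REM epoch of that pair and the first epoch of the
#' onset bout. While an event is awaiting its REM pair, later onsets do
#' not start new events. The per-period value is the mean over completed
#' events; periods with no qualifying REM pair give `NA`.
#'
#' @param hyp A [hypnogram()].
#' @param from_epoch,to_epoch 1-based period bounds (inclusive).
#' @param min_onset_epochs Consolidation criterion for sleep onset
#'   (default 3 epochs = 12 s).
#' @param min_rem_epochs REM criterion (default 2 epochs = 8 s).
#' @return List: `mean` (seconds, `NA` if no completed event),
#'   `latencies` (seconds per event), `onset_epochs` (period-relative
#'   1-based onset indices).
#' @export
rems_latency <- function(hyp, from_epoch = 1L, to_epoch = nrow(hyp),
                         min_onset_epochs = 3L, min_rem_epochs = 2L) {
  if (from_epoch > to_epoch) stop("empty period")
  if (from_epoch < 1L || to_epoch > nrow(hyp)) stop("period outside recording")
  st <- as_state_chr(hyp)[from_epoch:to_epoch]
  r <- rle(st)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  lat <- numeric(0); onsets <- integer(0)
  awaiting <- NA_integer_  # onset start index awaiting its REM pair
  for (j in seq_along(r$lengths)) {
    v <- r$values[j]
    if (!is.na(awaiting) && v == "REM" && r$lengths[j] >= min_rem_epochs) {
      lat <- c(lat, (starts[j] - awaiting) * EPOCH_SEC)
      onsets <- c(onsets, awaiting)
      awaiting <- NA_integer_
    } else if (is.na(awaiting) && v == "NREM" && r$lengths[j] >= min_onset_epochs) {
      if (j > 1L) {
        # preceding non-NREM run: contiguous non-NREM runs back to the
        # previous NREM run; onset qualifies if any of them is WAKE
        k <- j - 1L
        has_wake <- FALSE
        while (k >= 1L && r$values[k] != "NREM") {
          if (r$values[k] == "WAKE") has_wake <- TRUE
          k <- k - 1L
        }
        if (has_wake) awaiting <- starts[j]
      }
    }
  }
  list(mean = if (length(lat)) mean(lat) else NA_real_,
       latencies = lat, onset_epochs = onsets)
}

#' Transitions into and out of REM sleep
#'
#' Counts state boundaries entering REM and leaving REM, the latter keyed
#' by destination state. The totals can differ by at most one (a recording
#' may start or end within REM).
#'
#' @param hyp A [hypnogram()].
#' @return List: `into_rem` (count) and `out_of_rem` (named integer by
#'   destination state, empty if none).
#' @export
count_rem_transitions <- function(hyp) {
  st <- as_state_chr(hyp)
  n <- length(st)
  if (n == 0) stop("empty hypnogram")
  if (n == 1L) return(list(into_rem = 0L, out_of_rem = integer(0)))
  a <- st[-n]; b <- st[-1L]
  into <- sum(b == "REM" & a != "REM")
  out_idx <- which(a == "REM" & b != "REM")
  out <- table(factor(b[out_idx], levels = STATES))
  out <- out[out > 0]
  list(into_rem = as.integer(into),
       out_of_rem = setNames(as.integer(out), names(out)))
}
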