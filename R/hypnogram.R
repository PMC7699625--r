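#' @importFrom stats rnorm runif sd var mvfft fft setNames aggregate
NULL

# Canonical state labels, in scoring order.
STATES <- c("WAKE", "NREM", "REM", "CATAPLEXY")
STATE_CODES <- c(WAKE = "W", NREM = "N", REM = "R", CATAPLEXY = "C")
EPOCH_SEC <- 4
EPOCHS_PER_DAY <- 86400L / 4L  # 21600

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of scored vigilance states on a
#' fixed 4-s epoch grid, with an artifact flag per epoch and (optionally)
#' a theta-dominated-wakefulness (TDW) flag. It is stored as a data.frame
#' with one row per epoch and attributes carrying the epoch length and the
#' Zeitgeber alignment (`zt0_index`, the 1-based epoch index at which
#' lights-on / ZT0 falls; recordings normally start at lights-on, so the
#' default is 1).
#'
#' @param states Character or factor vector of states among
#'   `WAKE, NREM, REM, CATAPLEXY` (single-letter codes `W,N,R,C` accepted).
#' @param artifact Logical vector (recycled) flagging artifact epochs.
#' @param tdw Optional logical vector of TDW flags (only meaningful for
#'   WAKE epochs).
#' @param zt0_index 1-based epoch index of lights-on.
#' @return A data.frame of class `hypnogram` with columns `state`
#'   (factor), `artifact` (logical) and, when supplied, `tdw`.
#' @examples
#' h <- hypnogram(c("W", "W", "N", "N", "N", "R", "R"))
#' levels(h$state)
#' @export
hypnogram <- function(states, artifact = FALSE, tdw = NULL, zt0_index = 1L) {
  states <- as.character(states)
  decode <- setNames(STATES, STATE_CODES)
  short <- states %in% STATE_CODES
  states[short] <- decode[states[short]]
  bad <- which(!states %in% STATES)
  if (length(bad))
    stop("unknown state code '", states[bad[1]], "' at epoch ", bad[1])
  n <- length(states)
  if (n > 0 && (zt0_index < 1 || zt0_index > n))
    stop("zt0_index outside the recording")
  h <- data.frame(
    state = factor(states, levels = STATES),
    artifact = rep_len(as.logical(artifact), n)
  )
  if (!is.null(tdw)) h$tdw <- rep_len(as.logical(tdw), n)
  structure(h,
    class = c("hypnogram", "data.frame"),
    epoch_len = EPOCH_SEC, zt0_index = as.integer(zt0_index)
  )
}

#' Number of epochs in a hypnogram
#' @param hyp A [hypnogram()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(hyp) nrow(hyp)

#' Zeitgeber time of each epoch
#'
#' @param hyp A [hypnogram()].
#' @return Numeric vector: ZT in hours (in `[0, 24)`) of each epoch start,
#'   where ZT0 is lights-on and ZT12 lights-off.
#' @export
zt_hours <- function(hyp) {
  zt0 <- attr(hyp, "zt0_index")
  (((seq_len(nrow(hyp)) - zt0) * EPOCH_SEC / 3600) %% 24)
}

#' Light/dark phase of each epoch
#' @param hyp A [hypnogram()].
#' @return Character vector `"light"` (ZT0-12) or `"dark"` (ZT12-24).
#' @export
phase_of <- function(hyp) ifelse(zt_hours(hyp) < 12, "light", "dark")

#' Recording day of each epoch
#' @param hyp A [hypnogram()].
#' @return Integer vector: 1-based day index, days starting at ZT0.
#' @export
day_of <- function(hyp) {
  zt0 <- attr(hyp, "zt0_index")
  as.integer(floor((seq_len(nrow(hyp)) - zt0) * EPOCH_SEC / 86400)) + 1L
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", nrow(x), " epochs of ", attr(x, "epoch_len"),
      " s (", nrow(x) * attr(x, "epoch_len") / 3600, " h)\n", sep = "")
  tab <- table(x$state)
  cat("  states:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  artifacts:", sum(x$artifact), "\n")
  invisible(x)
}

# Internal: subsetting a hypnogram keeps its attributes only for
# contiguous head slices; analytics index into $state directly instead.
as_state_chr <- function(hyp) as.character(hyp$state)
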