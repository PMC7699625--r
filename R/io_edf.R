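#' Write a recording to European Data Format (EDF)
#'
#' Minimal EDF writer for the two-channel (EEG + EMG) recordings this
#' package produces: ASCII header, 1-second data records, 16-bit
#' little-endian samples, physical units uV with a symmetric physical
#' range per channel. The recording length must be a whole number of
#' seconds (always true for 4-s epoch grids).
#'
#' @param rec A `psg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  n_samp <- length(rec$eeg)
  if (n_samp != length(rec$emg)) stop("EEG and EMG lengths differ")
  if (n_samp %% fs != 0) stop("recording is not a whole number of seconds")
  n_rec <- n_samp %/% fs

  pad <- function(x, w) {
    x <- as.character(x)
    if (nchar(x) > w) stop("EDF header field too long: ", x)
    formatC(x, width = -w)
  }
  phys_max <- vapply(list(rec$eeg, rec$emg), function(x)
    max(1, ceiling(max(abs(x)))), numeric(1))
  gains <- 2 * phys_max / 65535  # EDF affine map: [-32768,32767] -> [-pm,pm]

  labels <- c("EEG", "EMG")
  header <- paste0(
    pad("0", 8), pad("synthetic mouse", 80), pad("somnoscope simulation", 80),
    pad("01.01.01", 8), pad("00.00.00", 8),
    pad(256 + 2 * 256, 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(2, 4),
    # per-signal fields, each field for all signals in turn
    paste0(vapply(labels, pad, "", w = 16), collapse = ""),
    paste0(vapply(c("synthetic", "synthetic"), pad, "", w = 80), collapse = ""),
    paste0(vapply(c("uV", "uV"), pad, "", w = 8), collapse = ""),
    paste0(vapply(-phys_max, pad, "", w = 8), collapse = ""),
    paste0(vapply(phys_max, pad, "", w = 8), collapse = ""),
    paste0(vapply(c(-32768, -32768), pad, "", w = 8), collapse = ""),
    paste0(vapply(c(32767, 32767), pad, "", w = 8), collapse = ""),
    paste0(vapply(c("", ""), pad, "", w = 80), collapse = ""),
    paste0(vapply(c(fs, fs), pad, "", w = 8), collapse = ""),
    paste0(vapply(c("", ""), pad, "", w = 32), collapse = "")
  )
  stopifnot(nchar(header) == 768)

  dig <- function(x, pm, gain) {
    d <- as.integer(round((x + pm) / gain)) - 32768L
    pmin(pmax(d, -32768L), 32767L)
  }
  eeg_d <- matrix(dig(rec$eeg, phys_max[1], gains[1]), fs, n_rec)
  emg_d <- matrix(dig(rec$emg, phys_max[2], gains[2]), fs, n_rec)
  interleaved <- as.integer(rbind(eeg_d, emg_d))  # per record: fs EEG then fs EMG

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(interleaved, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a two-channel EDF recording
#'
#' Counterpart of [write_edf()]: expects exactly one channel whose label
#' contains `EEG` and one containing `EMG`, equal sampling rates, and a
#' file length consistent with the header (a truncated file is a parse
#' error, never a partial object).
#'
#' @param path EDF file path.
#' @return A `psg_recording` (signals in uV).
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 2) stop("EDF must contain EEG and EMG channels")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                     # transducer
  for (i in seq_len(ns)) rd(8)                      # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                     # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)                     # reserved

  i_eeg <- grep("EEG", labels, ignore.case = TRUE)
  i_emg <- grep("EMG", labels, ignore.case = TRUE)
  if (length(i_eeg) != 1) stop("EDF is missing a unique EEG channel")
  if (length(i_emg) != 1) stop("EDF is missing a unique EMG channel: ",
                               paste(labels, collapse = ", "))
  if (spr[i_eeg] != spr[i_emg])
    stop("EEG and EMG sampling rates differ (", spr[i_eeg], " vs ", spr[i_emg], ")")
  expected <- header_bytes + as.numeric(n_rec) * sum(spr) * 2
  if (sz != expected)
    stop("EDF file length ", sz, " does not match header (expected ",
         expected, "); file truncated or corrupt")

  raw_all <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                     endian = "little")
  mat <- matrix(raw_all, sum(spr), n_rec)  # one column per record
  offs <- cumsum(c(0L, spr))
  take <- function(i) as.vector(mat[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  phys <- function(i) (take(i) - dmin[i]) * gain[i] + pmin_[i]
  fs <- as.integer(spr[i_eeg] / rec_dur)
  structure(list(eeg = phys(i_eeg), emg = phys(i_emg), fs = fs,
                 epoch_len = EPOCH_SEC, seed = NA_integer_),
            class = "psg_recording")
}

#' Write a hypnogram as TSV
#'
#' Columns: `epoch_index` (0-based), `zt_seconds` (seconds since the last
#' lights-on), `state` (single-letter `W`/`N`/`R`/`C`), `artifact`
#' (0/1) and, when present, `tdw` (0/1).
#'
#' @param hyp A [hypnogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(
    epoch_index = seq_len(nrow(hyp)) - 1L,
    zt_seconds = round(zt_hours(hyp) * 3600),
    state = STATE_CODES[as_state_chr(hyp)],
    artifact = as.integer(hyp$artifact)
  )
  if (!is.null(hyp$tdw)) df$tdw <- as.integer(hyp$tdw)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram TSV
#'
#' @param path TSV path, as written by [write_hypnogram()].
#' @param n_expected Optional epoch count of a paired recording; a
#'   mismatch is an error.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, n_expected = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(state = "character"))
  req <- c("epoch_index", "zt_seconds", "state", "artifact")
  if (!all(req %in% names(df)))
    stop("hypnogram TSV must have columns: ", paste(req, collapse = ", "))
  bad <- which(!df$state %in% STATE_CODES)
  if (length(bad))
    stop("unknown state code '", df$state[bad[1]], "' at row ", bad[1])
  if (!is.null(n_expected) && nrow(df) != n_expected)
    stop("hypnogram has ", nrow(df), " epochs but the recording has ",
         n_expected)
  zt0 <- which(df$zt_seconds == 0)
  hypnogram(df$state, artifact = df$artifact == 1,
            tdw = if ("tdw" %in% names(df)) df$tdw == 1 else NULL,
            zt0_index = if (length(zt0)) zt0[1] else 1L)
}
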