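# Independent brute-force oracles. These deliberately avoid rle()/vectorized
# shortcuts used by the implementation: plain per-epoch scans.

oracle_bouts <- function(st) {
  n <- length(st)
  if (n == 0)
    return(data.frame(state = character(), start_epoch = integer(),
                      n_epochs = integer(), duration = numeric()))
  starts <- c(); lens <- c(); vals <- c()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && st[j + 1L] == st[i]) j <- j + 1L
    starts <- c(starts, i); lens <- c(lens, j - i + 1L); vals <- c(vals, st[i])
    i <- j + 1L
  }
  data.frame(state = vals, start_epoch = starts, n_epochs = lens,
             duration = lens * 4)
}

oracle_scorable <- function(st, art, state) {
  n <- length(st)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    win <- (i - 1L):(i + 1L)
    if (all(st[win] == state) && all(!art[win])) out <- c(out, i)
  }
  out
}

oracle_transitions <- function(st) {
  into <- 0L; out <- c()
  for (i in seq_len(length(st) - 1L)) {
    if (st[i + 1L] == "REM" && st[i] != "REM") into <- into + 1L
    if (st[i] == "REM" && st[i + 1L] != "REM") out <- c(out, st[i + 1L])
  }
  list(into = into, out = out)
}

oracle_latency <- function(st, min_onset = 3L, min_rem = 2L) {
  n <- length(st)
  lats <- numeric(0); awaiting <- NA_integer_
  for (i in seq_len(n)) {
    at_run_start <- i == 1L || st[i - 1L] != st[i]
    if (!at_run_start) next
    L <- 1L; while (i + L <= n && st[i + L] == st[i]) L <- L + 1L
    if (!is.na(awaiting)) {
      if (st[i] == "REM" && L >= min_rem) {
        lats <- c(lats, (i - awaiting) * 4)
        awaiting <- NA_integer_
      }
    } else if (st[i] == "NREM" && L >= min_onset && i > 1L) {
      k <- i - 1L; has_wake <- FALSE
      while (k >= 1L && st[k] != "NREM") {
        if (st[k] == "WAKE") has_wake <- TRUE
        k <- k - 1L
      }
      if (has_wake) awaiting <- i
    }
  }
  lats
}

random_states <- function(n, p = c(0.4, 0.35, 0.15, 0.1)) {
  sample(c("WAKE", "NREM", "REM", "CATAPLEXY"), n, replace = TRUE, prob = p)
}
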