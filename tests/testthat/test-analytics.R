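test_that("bout detection matches hand-counted runs and tiles the hypnogram", {
  h <- hypnogram(c("N", "N", "R", "R", "R", "W"))
  b <- detect_bouts(h)
  expect_equal(b$state, c("NREM", "REM", "WAKE"))
  expect_equal(b$duration, c(8, 12, 4))
  expect_equal(b$start_epoch, c(1, 3, 6))
  expect_equal(nrow(detect_bouts(hypnogram(character(0)))), 0)
  expect_error(detect_bouts(h, "DOZE"))
  # tiling invariant
  expect_equal(sum(b$duration), nrow(h) * 4)
})

test_that("bout detection equals the run-length oracle on random hypnograms", {
  set.seed(101)
  for (i in 1:300) {
    st <- random_states(sample(1:120, 1))
    got <- detect_bouts(hypnogram(st))
    want <- oracle_bouts(st)
    expect_equal(got, want)
    expect_equal(sum(got$duration), length(st) * 4)
  }
})

test_that("bout duration histogram bins by lower edge and conserves counts", {
  r <- bout_duration_histogram(c(8, 12, 16, 300))
  expect_equal(unname(r$counts), c(2, 1, 0, 0, 0, 1))
  expect_equal(r$sub_threshold, 0)
  r2 <- bout_duration_histogram(4)
  expect_equal(sum(r2$counts), 0)
  expect_equal(r2$sub_threshold, 1)
  expect_error(bout_duration_histogram(8, bin_lowers = c(8, 8)), "increasing")
  set.seed(5)
  for (i in 1:50) {
    dur <- sample(seq(4, 600, 4), 40, replace = TRUE)
    r <- bout_duration_histogram(dur)
    expect_equal(sum(r$counts) + r$sub_threshold, 40)
  }
})

test_that("long REM bout counting is strict at the threshold", {
  expect_equal(long_rem_bout_count(c(120, 124)), 1)
  expect_equal(long_rem_bout_count(numeric(0)), 0)
  set.seed(6)
  dur <- sample(seq(4, 400, 4), 200, replace = TRUE)
  expect_equal(long_rem_bout_count(dur), sum(dur > 120))
})

test_that("state time-course returns minutes per hour averaged over windows", {
  # strict alternation: 30 min/h each state in every 2-h window
  h <- hypnogram(rep(c("W", "N"), 21600 / 2))
  for (s in c("WAKE", "NREM")) {
    tc <- state_time_course(h, s)
    expect_equal(tc$minutes_per_hour, rep(30, 12))
    expect_equal(tc$zt_center, seq(1, 23, 2))
  }
  # an all-REM hour scores 60 min/h
  h2 <- hypnogram(rep("R", 900))
  expect_equal(state_time_course(h2, "REM", window_hours = 1)$minutes_per_hour, 60)
  expect_error(state_time_course(hypnogram(rep("R", 10)), "REM"), "whole hours")
  # brute-force per-hour count oracle
  set.seed(7)
  st <- random_states(2 * 3600 / 4)
  h3 <- hypnogram(st)
  tc <- state_time_course(h3, "NREM", window_hours = 1)
  manual <- c(sum(st[1:900] == "NREM"), sum(st[901:1800] == "NREM")) * 4 / 60
  expect_equal(tc$minutes_per_hour, manual)
})

test_that("day averaging folds the time-course across days", {
  st <- c(rep("W", 21600), rep("N", 21600))
  h <- hypnogram(st)
  tc <- state_time_course(h, "WAKE", window_hours = 2, average_days = TRUE)
  expect_equal(tc$minutes_per_hour, rep(30, 12))
})

test_that("REM latency matches the hand example and handles missing REM", {
  h <- hypnogram(c("W", "W", "N", "N", "N", "R", "R"))
  r <- rems_latency(h)
  expect_equal(r$latencies, 12)
  expect_equal(r$mean, 12)
  # no REM pair: undefined, not zero
  h2 <- hypnogram(c("W", "N", "N", "N", "W", "R"))
  expect_true(is.na(rems_latency(h2)$mean))
  # cataplexy neither qualifies as wake precedence nor breaks NREM runs
  h3 <- hypnogram(c("C", "C", "N", "N", "N", "R", "R"))
  expect_true(is.na(rems_latency(h3)$mean))
  expect_error(rems_latency(h, 5, 2), "empty period")
})

test_that("REM latency equals the per-epoch scan oracle on random hypnograms", {
  set.seed(103)
  for (i in 1:500) {
    st <- random_states(sample(20:200, 1), p = c(0.35, 0.35, 0.2, 0.1))
    got <- rems_latency(hypnogram(st))
    want <- oracle_latency(st)
    expect_equal(got$latencies, want)
    expect_equal(got$mean, if (length(want)) mean(want) else NA_real_)
  }
})

test_that("REM transition counts match the pairwise-boundary oracle", {
  r <- count_rem_transitions(hypnogram(c("N", "R", "W", "R", "N")))
  expect_equal(r$into_rem, 2)
  expect_equal(r$out_of_rem, c(WAKE = 1L, NREM = 1L))
  r2 <- count_rem_transitions(hypnogram(rep("R", 5)))
  expect_equal(r2$into_rem, 0)
  expect_length(r2$out_of_rem, 0)
  set.seed(104)
  for (i in 1:300) {
    st <- random_states(sample(2:150, 1))
    got <- count_rem_transitions(hypnogram(st))
    want <- oracle_transitions(st)
    expect_equal(got$into_rem, want$into)
    expect_equal(sum(got$out_of_rem), length(want$out))
    # in/out totals never differ by more than one
    expect_lte(abs(got$into_rem - sum(got$out_of_rem)), 1)
  }
})
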