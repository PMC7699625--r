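test_that("simulation is deterministic under a seed and respects rate zero", {
  p <- genotype_presets("WT")
  h1 <- simulate_hypnogram(p, days = 1, seed = 7)
  h2 <- simulate_hypnogram(p, days = 1, seed = 7)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 21600L)
  # intact-HCRT preset never emits cataplexy
  expect_equal(sum(h1$state == "CATAPLEXY"), 0L)
  h3 <- simulate_hypnogram(p, days = 1, seed = 8)
  expect_false(identical(as.character(h1$state), as.character(h3$state)))
})

test_that("cataplexy obeys entry, duration and precedence rules", {
  p <- genotype_presets("HcrtKO")
  h <- simulate_hypnogram(p, days = 3, seed = 21)
  bouts <- detect_bouts(h)
  ci <- which(bouts$state == "CATAPLEXY")
  expect_gt(length(ci), 0)
  # minimum 3 epochs (12 s)
  expect_true(all(bouts$n_epochs[ci] >= 3))
  # entered only from WAKE, exits only to WAKE, >= 40 s prior wakefulness
  for (j in ci) {
    expect_identical(bouts$state[j - 1], "WAKE")
    expect_gte(bouts$n_epochs[j - 1], 10)
    if (j < nrow(bouts)) expect_identical(bouts$state[j + 1], "WAKE")
  }
})

test_that("REM is entered only from NREM", {
  for (g in c("WT", "HcrtKO", "DKO")) {
    h <- simulate_hypnogram(genotype_presets(g), days = 1, seed = 3)
    st <- as.character(h$state)
    pre <- st[which(st[-1] == "REM" & st[-length(st)] != "REM")]
    expect_true(all(pre == "NREM"), label = paste(g, "REM entry from NREM"))
  }
})

test_that("long-run occupancies match the embedded-chain stationary fractions", {
  # phase-constant parameters so one analytic answer covers the whole run
  p <- genotype_presets("WT")
  p$dwell_mean$dark <- p$dwell_mean$light
  p$p_rem_entry["dark"] <- p$p_rem_entry["light"]
  p$p_rem_exit_wake["dark"] <- p$p_rem_exit_wake["light"]
  h <- simulate_hypnogram(p, days = 30, seed = 77)
  theo <- stationary_occupancy(p, "light")
  d <- day_of(h)
  for (s in c("WAKE", "NREM", "REM")) {
    daily <- vapply(split(as.character(h$state) == s, d), mean, numeric(1))
    se <- sd(daily) / sqrt(length(daily))
    expect_lt(abs(mean(daily) - theo[[s]]), 3 * se + 1e-12,
              label = paste("occupancy of", s))
  }
})

test_that("doubling the REM dwell mean increases detected REM bout duration", {
  p1 <- genotype_presets("WT")
  p2 <- p1
  p2$dwell_mean$light["REM"] <- 2 * p1$dwell_mean$light["REM"]
  p2$dwell_mean$dark["REM"] <- 2 * p1$dwell_mean$dark["REM"]
  m1 <- mean(detect_bouts(simulate_hypnogram(p1, 3, seed = 9), "REM")$duration)
  m2 <- mean(detect_bouts(simulate_hypnogram(p2, 3, seed = 9), "REM")$duration)
  expect_gt(m2, m1)
})

test_that("sleep deprivation forces WAKE in-window and nothing else", {
  p <- genotype_presets("WT")
  h <- simulate_hypnogram(p, days = 2, seed = 11)
  h2 <- apply_sleep_deprivation(h, day = 2, start_zt = 0, duration = 6)
  win <- epochs_in(h, day = 2, zt_from = 0, zt_to = 6)
  expect_true(all(h2$state[win] == "WAKE"))
  expect_identical(as.character(h2$state[-win]), as.character(h$state[-win]))
  # zero duration is the identity
  expect_identical(apply_sleep_deprivation(h, 1, 0, 0), h)
  expect_error(apply_sleep_deprivation(h, 3, 0, 6), "outside")
})

test_that("Process S is bounded, monotone per run, and SD raises it at ZT6", {
  p <- genotype_presets("WT")
  h <- simulate_hypnogram(p, days = 2, seed = 13)
  s <- process_s(h)
  expect_true(all(s >= 0 & s <= 1))
  b <- detect_bouts(h)
  for (j in head(seq_len(nrow(b)), 200)) {
    seg <- s[b$start_epoch[j]:(b$start_epoch[j] + b$n_epochs[j] - 1L)]
    if (b$state[j] == "NREM") expect_true(all(diff(seg) <= 0))
    else expect_true(all(diff(seg) >= 0))
  }
  # SD keeps pressure high: S at ZT6 of the deprived day exceeds baseline
  h_sd <- apply_sleep_deprivation(h, day = 2)
  i_zt6 <- epochs_in(h, day = 2, zt_from = 6, zt_to = 24)[1] - 1L
  expect_gt(process_s(h_sd)[i_zt6], s[i_zt6])
})

test_that("artifact marking flags the exact count and nothing else changes", {
  h <- simulate_hypnogram(genotype_presets("WT"), days = 1, seed = 15)
  h0 <- mark_artifacts(h, 0, seed = 1)
  expect_equal(sum(h0$artifact), 0)
  h1 <- mark_artifacts(h, 0.1, seed = 1)
  expect_equal(sum(h1$artifact), round(0.1 * nrow(h)))
  expect_identical(as.character(h1$state), as.character(h$state))
  expect_identical(mark_artifacts(h, 0.1, seed = 1), h1)
  expect_error(mark_artifacts(h, 1, seed = 1), "fraction")
  # flagged epochs disappear from scorable selections
  flagged <- which(h1$artifact)
  expect_length(intersect(select_scorable_epochs(h1, "NREM"), flagged), 0)
})

test_that("parameter validation rejects inconsistent presets", {
  expect_error(genotype_params("x",
    dwell_mean = list(light = c(WAKE = 2, NREM = 220, REM = 70),
                      dark = c(WAKE = 600, NREM = 180, REM = 60)),
    p_rem_entry = c(light = 0.4, dark = 0.2)), "dwell")
  expect_error(genotype_params("x",
    dwell_mean = list(light = c(WAKE = 200, NREM = 220, REM = 70),
                      dark = c(WAKE = 600, NREM = 180, REM = 60)),
    p_rem_entry = c(light = 1.4, dark = 0.2)), "probabilit")
  expect_error(genotype_params("x",
    dwell_mean = list(light = c(WAKE = 200, NREM = 220, REM = 70),
                      dark = c(WAKE = 600, NREM = 180, REM = 60)),
    p_rem_entry = c(light = 0.4, dark = 0.2), theta_peak_hz = 11), "theta")
})
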