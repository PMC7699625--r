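make_rec <- function(eeg, fs) {
  structure(list(eeg = eeg, emg = numeric(length(eeg)), fs = fs,
                 epoch_len = 4), class = "psg_recording")
}

sine <- function(f, fs, secs = 4, a = 1, phase = 0) {
  a * sin(2 * pi * f * (0:(secs * fs - 1)) / fs + phase)
}

test_that("a bin-aligned sinusoid lands all its power in one bin", {
  fs <- 200
  sp <- epoch_spectra(make_rec(sine(10, fs, a = 3), fs))
  expect_equal(dim(sp$power), c(1, 361))
  expect_equal(sp$freq[which.max(sp$power)], 10)
  expect_equal(sp$power[1, sp$freq == 10], 3^2 / 2, tolerance = 1e-10)
  expect_equal(sum(sp$power) - sp$power[1, sp$freq == 10], 0, tolerance = 1e-10)
  # zero signal gives all-zero spectra
  expect_true(all(epoch_spectra(make_rec(numeric(800), fs))$power == 0))
  expect_error(epoch_spectra(make_rec(numeric(400), 100)), "fs")
  expect_error(epoch_spectra(make_rec(numeric(801), 200)), "whole number")
})

test_that("white-noise total power satisfies Parseval within 2%", {
  set.seed(31)
  fs <- 180  # 90 Hz bins span the whole one-sided spectrum at fs = 180
  x <- rnorm(720 * 500, sd = 2)
  sp <- epoch_spectra(make_rec(x, fs))
  expect_equal(mean(rowSums(sp$power)), var(x), tolerance = 0.02)
})

test_that("EEG amplitude scaling is quadratic in power, exact under a shared seed", {
  p <- genotype_presets("WT")
  h <- hypnogram(rep(c("W", "N", "R"), each = 450))
  p2 <- p
  p2$band_gains <- lapply(p$band_gains, function(g) 2 * g)
  p2$noise_amp <- 2 * p$noise_amp
  r1 <- synthesize_signals(h, p, fs = 200, seed = 5)
  r2 <- synthesize_signals(h, p2, fs = 200, seed = 5)
  expect_equal(r2$eeg, 2 * r1$eeg, tolerance = 1e-12)
  s1 <- epoch_spectra(r1); s2 <- epoch_spectra(r2)
  expect_equal(s2$power, 4 * s1$power, tolerance = 1e-12)
})

test_that("scorable-epoch selection applies the triple-window rule", {
  h <- hypnogram(c("N", "N", "N"))
  expect_equal(select_scorable_epochs(h, "NREM"), 2L)
  h2 <- hypnogram(c("N", "N", "N"), artifact = c(FALSE, TRUE, FALSE))
  expect_length(select_scorable_epochs(h2, "NREM"), 0)
  set.seed(32)
  for (i in 1:300) {
    st <- random_states(sample(3:100, 1))
    art <- runif(length(st)) < 0.15
    h3 <- hypnogram(st, artifact = art)
    for (s in c("WAKE", "REM")) {
      expect_equal(select_scorable_epochs(h3, s), oracle_scorable(st, art, s))
    }
  }
})

test_that("adding artifacts only ever shrinks the scorable set", {
  h <- simulate_hypnogram(genotype_presets("WT"), days = 1, seed = 33)
  sel0 <- select_scorable_epochs(h, "NREM")
  h1 <- mark_artifacts(h, 0.05, seed = 1)
  sel1 <- select_scorable_epochs(h1, "NREM")
  h2 <- mark_artifacts(h1, 0.2, seed = 2)
  sel2 <- select_scorable_epochs(h2, "NREM")
  expect_true(all(sel1 %in% sel0))
  expect_true(all(sel2 %in% sel1))
})

test_that("state mean spectrum is the arithmetic mean; empty selection is NA", {
  pw <- matrix(runif(5 * 361), 5, 361)
  sp <- structure(list(power = pw, freq = seq(0, 90, 0.25), fs = 200),
                  class = "epoch_spectra")
  expect_equal(state_mean_spectrum(sp, 3L), pw[3, ])
  expect_equal(state_mean_spectrum(sp, c(1L, 4L)), (pw[1, ] + pw[4, ]) / 2)
  expect_warning(res <- state_mean_spectrum(sp, integer(0)), "absent")
  expect_true(all(is.na(res)))
})

test_that("baseline reference reproduces a hand-computed weighted mean", {
  # three states, constant within state: WAKE rows 10, NREM rows 20, REM 5
  st <- rep(c("WAKE", "NREM", "REM"), each = 5)
  h <- hypnogram(st)
  pw <- matrix(0, 15, 361)
  lvl <- c(WAKE = 10, NREM = 20, REM = 5)
  pw[] <- lvl[st] / 188  # 188 bins lie in 0.75-47.5 Hz
  sp <- structure(list(power = pw, freq = seq(0, 90, 0.25), fs = 200),
                  class = "epoch_spectra")
  w <- c(WAKE = 0.5, NREM = 0.4, REM = 0.1)
  ref <- baseline_reference(sp, h, weights = w)
  expect_equal(ref$value, sum(w * lvl), tolerance = 1e-9)
  # normalizing the per-state powers gives back percentages of that value
  expect_equal(normalize_spectrum(ref$per_state_power, ref),
               100 * lvl / sum(w * lvl), tolerance = 1e-9)
  expect_error(baseline_reference(sp, h, weights = c(WAKE = 1, NREM = 1, REM = 1)),
               "sum to 1")
  # a state with no scorable epochs is an error naming the state
  h2 <- hypnogram(c(rep("WAKE", 6), rep("NREM", 6), "REM", "WAKE", "REM"))
  sp2 <- structure(list(power = matrix(1, 15, 361), freq = seq(0, 90, 0.25),
                        fs = 200), class = "epoch_spectra")
  expect_error(baseline_reference(sp2, h2), "REM")
})

test_that("normalization is scale invariant and anchored at 100%", {
  spec <- runif(361)
  ref <- sum(spec[seq(0, 90, 0.25) >= 0.75 & seq(0, 90, 0.25) <= 47.5])
  ns <- normalize_spectrum(spec, ref)
  expect_equal(sum(ns[seq(0, 90, 0.25) >= 0.75 & seq(0, 90, 0.25) <= 47.5]), 100)
  expect_equal(normalize_spectrum(2 * spec, 2 * ref), ns)
  expect_equal(normalize_spectrum(spec, ref), spec * 100 / ref)
  expect_error(normalize_spectrum(spec, 0), "reference")
})

test_that("band power sums inclusive edges", {
  flat <- rep(1, 361)
  expect_equal(band_power(flat, eeg_bands("delta")), 13)  # 1-4 Hz inclusive
  expect_equal(band_power(flat, band("one", 5, 5)), 1)
  expect_error(band("bad", -1, 4))
  expect_error(band("bad", 5, 95))
  set.seed(34)
  for (i in 1:50) {
    spec <- runif(361)
    lo <- sample(seq(0, 80, 0.25), 1); hi <- lo + sample(seq(0, 9, 0.25), 1)
    f <- seq(0, 90, 0.25)
    expect_equal(band_power(spec, band("x", lo, hi)), sum(spec[f >= lo & f <= hi]))
  }
})

test_that("theta peak frequency recovers planted peaks and breaks ties low", {
  fs <- 200
  for (f0 in c(6, 7.5, 8.25, 9.75)) {
    sp <- epoch_spectra(make_rec(sine(f0, fs), fs))
    expect_equal(theta_peak_frequency(sp$power[1, ]), f0)
  }
  spec <- rep(0, 361)
  spec[seq(0, 90, 0.25) %in% c(7, 8)] <- 5
  expect_equal(theta_peak_frequency(spec), 7)
  expect_warning(theta_peak_frequency(rep(1, 361)), "flat")
})
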