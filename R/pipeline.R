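#' Build a pipeline run configuration
#'
#' Describes either a simulated cohort (genotype presets and replicate
#' counts) or a set of recorded mice (EDF + hypnogram TSV paths), plus the
#' protocol (days, SD day) and analysis parameters. All defaults follow
#' the standard conventions: 4-s epochs, 0-90 Hz spectra at 0.25 Hz,
#' 0.75-47.5 Hz state-weighted baseline reference, the canonical
#' percentile scheme and the self-calibrating cataplexy thresholds.
#'
#' @param out_dir Output directory for CSV tables.
#' @param genotypes Character vector of preset names (see
#'   [genotype_presets()]).
#' @param n_per_genotype Replicates per genotype.
#' @param days Recording days per mouse.
#' @param sd_day Day of the 6-h ZT0-6 sleep deprivation (`NULL` = none).
#' @param fs Sampling rate, Hz.
#' @param seed Master integer seed; every mouse derives its own seeds
#'   from it.
#' @param artifact_fraction Fraction of epochs flagged as artifacts.
#' @param mice Optional list of recorded mice, each a list with `id`,
#'   `genotype`, `edf`, `hypnogram`; overrides simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       genotypes = c("WT", "HcrtKO", "X5HTTKO",
                                     "X5HTThet_HcrtKO", "DKO"),
                       n_per_genotype = 4L,
                       days = 3L, sd_day = 3L, fs = 200L, seed = 1L,
                       artifact_fraction = 0.02,
                       mice = NULL) {
  cfg <- list(out_dir = out_dir, genotypes = genotypes,
              n_per_genotype = as.integer(n_per_genotype),
              days = as.integer(days),
              sd_day = if (is.null(sd_day)) NULL else as.integer(sd_day),
              fs = as.integer(fs), seed = as.integer(seed),
              artifact_fraction = artifact_fraction,
              epoch_len = EPOCH_SEC, mice = mice)
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration (YAML)
#'
#' `save_config()` and `load_config()` round-trip a [run_config()]
#' losslessly.
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `load_config()` returns the `run_config`; `save_config()` the
#'   path, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$n_per_genotype <- as.integer(cfg$n_per_genotype)
  cfg$days <- as.integer(cfg$days)
  if (!is.null(cfg$sd_day)) cfg$sd_day <- as.integer(cfg$sd_day)
  cfg$fs <- as.integer(cfg$fs)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Analyze one mouse end to end
#'
#' Runs every analytic stage on one recording: state time-courses
#' (including TDW and cataplexy minutes), bout statistics and duration
#' histograms, long REM bout counts, REM latency (baseline dark and
#' post-SD), REM transitions, normalized state spectra, theta peak
#' frequency, band-power percentile time-courses (NREM delta in ZT8-12
#' units, REM theta and WAKE fast-gamma in state-baseline units) and
#' cataplexy detection.
#'
#' @param hyp A [hypnogram()].
#' @param rec The matching `psg_recording`.
#' @param spec Optional precomputed [epoch_spectra()].
#' @param sd_day SD day or `NULL`.
#' @param ref_weights Cohort state weights for [baseline_reference()]
#'   (`NULL`: the mouse's own fractions).
#' @return Named list of data.frames / scalars.
#' @export
analyze_mouse <- function(hyp, rec, spec = NULL, sd_day = NULL,
                          ref_weights = NULL) {
  if (is.null(spec)) spec <- epoch_spectra(rec)
  days <- nrow(hyp) %/% EPOCHS_PER_DAY
  baseline_days <- if (is.null(sd_day)) seq_len(days) else seq_len(sd_day - 1L)

  # --- architecture ---
  tc <- do.call(rbind, lapply(c("WAKE", "NREM", "REM", "CATAPLEXY", "TDW"),
    function(s) {
      if (s == "TDW" && is.null(hyp$tdw)) return(NULL)
      cbind(state = s, state_time_course(hyp, s, window_hours = 2))
    }))

  bouts <- detect_bouts(hyp)
  phase <- phase_of(hyp)[bouts$start_epoch]
  bl <- day_of(hyp)[bouts$start_epoch] %in% baseline_days
  bout_stats <- aggregate(duration ~ state + phase,
                          data = cbind(bouts, phase = phase)[bl, ],
                          FUN = function(d) c(n = length(d), mean_s = mean(d)))
  bout_stats <- data.frame(state = bout_stats$state, phase = bout_stats$phase,
                           n = bout_stats$duration[, "n"],
                           mean_s = bout_stats$duration[, "mean_s"])

  rem_dark_bl <- bouts[bouts$state == "REM" & phase == "dark" & bl, ]
  hist_rem <- bout_duration_histogram(rem_dark_bl)
  n_long_rem <- long_rem_bout_count(rem_dark_bl)

  lat_dark <- unlist(lapply(baseline_days, function(d) {
    idx <- epochs_in(hyp, day = d, zt_from = 12, zt_to = 24)
    rems_latency(hyp, min(idx), max(idx))$latencies
  }))
  lat_sd <- if (!is.null(sd_day)) {
    idx <- epochs_in(hyp, day = sd_day, zt_from = 6, zt_to = 24)
    rems_latency(hyp, min(idx), max(idx))$latencies
  } else numeric(0)

  trans <- count_rem_transitions(hyp)

  # --- spectra ---
  ref <- baseline_reference(spec, hyp, weights = ref_weights,
                            day = baseline_days[1])
  spectra <- do.call(rbind, lapply(c("WAKE", "NREM", "REM"), function(s) {
    idx <- select_scorable_epochs(hyp, s)
    idx <- idx[day_of(hyp)[idx] %in% baseline_days]
    if (!length(idx)) return(NULL)
    data.frame(state = s, freq = spec$freq,
               power_percent = normalize_spectrum(
                 state_mean_spectrum(spec, idx), ref),
               power_uv2 = state_mean_spectrum(spec, idx))
  }))

  rem_idx <- select_scorable_epochs(hyp, "REM")
  rem_dark <- rem_idx[phase_of(hyp)[rem_idx] == "dark" &
                        day_of(hyp)[rem_idx] %in% baseline_days]
  tpf <- if (length(rem_dark)) {
    theta_peak_frequency(state_mean_spectrum(spec, rem_dark))
  } else NA_real_

  # --- dynamics ---
  tc_delta <- band_power_timecourse(spec, hyp, "NREM", eeg_bands("delta"),
                                    mode = "zt8_12_delta", sd_day = sd_day)
  tc_theta <- band_power_timecourse(spec, hyp, "REM", eeg_bands("theta"),
                                    mode = "state_baseline", sd_day = sd_day)
  tc_gamma <- band_power_timecourse(spec, hyp, "WAKE", eeg_bands("fast_gamma"),
                                    mode = "state_baseline", sd_day = sd_day)
  band_tc <- rbind(cbind(state = "NREM", bd = "delta", mode = "zt8_12_delta",
                         tc_delta),
                   cbind(state = "REM", bd = "theta", mode = "state_baseline",
                         tc_theta),
                   cbind(state = "WAKE", bd = "fast_gamma",
                         mode = "state_baseline", tc_gamma))

  # --- cataplexy ---
  cata <- detect_cataplexy(rec, hyp, spec)
  cata_day <- if (nrow(cata)) day_of(hyp)[cata$start_epoch] else integer(0)
  cata_phase <- if (nrow(cata)) phase_of(hyp)[cata$start_epoch] else character(0)
  cata$interval <- if (nrow(cata)) {
    ifelse(cata_phase == "light",
           ifelse(cata_day %in% baseline_days, "baseline_light", "recovery_light"),
           ifelse(cata_day %in% baseline_days, "baseline_dark", "recovery_dark"))
  } else character(0)

  list(
    time_course = tc,
    bout_stats = bout_stats,
    rem_hist = data.frame(bin_lower_s = names(hist_rem$counts),
                          count = as.integer(hist_rem$counts)),
    n_long_rem_dark = n_long_rem,
    latency_dark_s = if (length(lat_dark)) mean(lat_dark) else NA_real_,
    latency_post_sd_s = if (length(lat_sd)) mean(lat_sd) else NA_real_,
    transitions = data.frame(
      metric = c("into_rem", paste0("rem_to_", names(trans$out_of_rem))),
      count = c(trans$into_rem, as.integer(trans$out_of_rem))),
    reference_uv2 = ref$value,
    spectra = spectra,
    tpf_hz = tpf,
    band_timecourse = band_tc,
    cataplexy = cata
  )
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) every mouse in the configuration, runs
#' [analyze_mouse()] on each, and writes tidy CSV tables to
#' `cfg$out_dir`: `state_timecourse.csv`, `bout_stats.csv`,
#' `rem_bout_histogram.csv`, `latency.csv`, `transitions.csv`,
#' `spectra.csv`, `tpf.csv`, `band_timecourse.csv`, `cataplexy.csv` and a
#' per-genotype `group_summary.csv` (mean, SD, SEM of the scalar
#' metrics). Deterministic: the same configuration and seed give
#' byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the list of per-mouse result lists.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  roster <- if (!is.null(cfg$mice)) {
    lapply(cfg$mice, function(m) m)
  } else {
    idx <- 0L
    unlist(lapply(cfg$genotypes, function(g)
      lapply(seq_len(cfg$n_per_genotype), function(i) {
        list(id = paste0(g, "_", i), genotype = g, rep = i)
      })), recursive = FALSE)
  }

  results <- vector("list", length(roster))
  names(results) <- vapply(roster, `[[`, "", "id")
  for (k in seq_along(roster)) {
    m <- roster[[k]]
    say("[", m$id, "] simulate/load")
    if (!is.null(m$edf)) {
      rec <- read_edf(m$edf)
      hyp <- read_hypnogram(m$hypnogram,
                            n_expected = length(rec$eeg) / (EPOCH_SEC * rec$fs))
      sd_day <- cfg$sd_day
    } else {
      params <- genotype_presets(m$genotype)
      seed_m <- cfg$seed + 1000L * k
      hyp <- simulate_hypnogram(params, cfg$days, seed = seed_m)
      if (!is.null(cfg$sd_day))
        hyp <- apply_sleep_deprivation(hyp, cfg$sd_day)
      if (cfg$artifact_fraction > 0)
        hyp <- mark_artifacts(hyp, cfg$artifact_fraction, seed = seed_m + 1L)
      rec <- synthesize_signals(hyp, params, fs = cfg$fs, seed = seed_m + 2L)
      sd_day <- cfg$sd_day
    }
    say("[", m$id, "] spectra + analytics")
    res <- analyze_mouse(hyp, rec, sd_day = sd_day)
    res$id <- m$id
    res$genotype <- m$genotype
    results[[k]] <- res
    rm(rec, hyp); gc(verbose = FALSE)
  }

  tag <- function(field) do.call(rbind, lapply(results, function(r)
    if (!is.null(r[[field]]) && nrow(r[[field]]))
      cbind(id = r$id, genotype = r$genotype, r[[field]])))
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(cfg$out_dir, f), row.names = FALSE)

  wr(tag("time_course"), "state_timecourse.csv")
  wr(tag("bout_stats"), "bout_stats.csv")
  wr(tag("rem_hist"), "rem_bout_histogram.csv")
  wr(tag("transitions"), "transitions.csv")
  wr(tag("spectra"), "spectra.csv")
  wr(tag("band_timecourse"), "band_timecourse.csv")
  cata <- tag("cataplexy")
  wr(if (is.null(cata)) data.frame() else cata, "cataplexy.csv")

  scalars <- do.call(rbind, lapply(results, function(r) data.frame(
    id = r$id, genotype = r$genotype,
    n_long_rem_dark = r$n_long_rem_dark,
    latency_dark_s = r$latency_dark_s,
    latency_post_sd_s = r$latency_post_sd_s,
    reference_uv2 = r$reference_uv2,
    tpf_hz = r$tpf_hz,
    n_cataplexy = nrow(r$cataplexy)
  )))
  wr(scalars, "mouse_metrics.csv")

  metrics <- setdiff(names(scalars), c("id", "genotype"))
  summ <- do.call(rbind, lapply(split(scalars, scalars$genotype), function(d)
    do.call(rbind, lapply(metrics, function(mt) {
      v <- d[[mt]][is.finite(d[[mt]])]
      data.frame(genotype = d$genotype[1], metric = mt,
                 n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
    }))))
  rownames(summ) <- NULL
  wr(summ, "group_summary.csv")
  say("pipeline complete: ", cfg$out_dir)
  invisible(results)
}
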