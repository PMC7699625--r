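# Session-level cache of the expensive simulated fixtures, so several test
# files can share one synthesis run. All seeds are fixed.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  .fixtures[[name]] <- switch(name,
    # WT mouse, 2 baseline days + SD day (ZT0-6), full signals + spectra
    wt3 = local({
      p <- genotype_presets("WT")
      hyp <- simulate_hypnogram(p, days = 3, seed = 41)
      hyp <- apply_sleep_deprivation(hyp, day = 3)
      hyp <- mark_artifacts(hyp, 0.02, seed = 42)
      rec <- synthesize_signals(hyp, p, fs = 200, seed = 43)
      list(params = p, hyp = hyp, rec = rec, spec = epoch_spectra(rec))
    }),
    # narcoleptic mouse, 2 days, for cataplexy/TDW work
    hcrt2 = local({
      p <- genotype_presets("HcrtKO")
      hyp <- simulate_hypnogram(p, days = 2, seed = 51)
      rec <- synthesize_signals(hyp, p, fs = 200, seed = 52)
      list(params = p, hyp = hyp, rec = rec, spec = epoch_spectra(rec))
    }),
    stop("unknown fixture: ", name)
  )
  .fixtures[[name]]
}

# epoch ranges covered by episodes/bouts, for overlap matching
episode_epochs <- function(df) {
  if (!nrow(df)) return(integer(0))
  unlist(mapply(function(a, b) a:b, df$start_epoch,
                df$start_epoch + df$n_epochs - 1L, SIMPLIFY = FALSE))
}
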