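#!/usr/bin/env Rscript
# Pheromone dose-response: Hill fits and CI-overlap comparisons.
#
# Simulates 9-replicate reporter plates on the half-log dose ladder for the
# control and each transcription preset, normalizes fluorescence to culture
# density, fits per-group Hill curves, and compares Emax / EC50 by 95%
# CI overlap. Recovered percent changes are means over 20 simulated plate
# pairs (a single pair is unbiased but has a few percent sampling error).

suppressMessages(library(gpcrtraffic))

seed <- 20260903
dir.create("results", showWarnings = FALSE)

rows <- list()
for (preset in c("rapamycin_transcription", "ypk1_delta",
                 "atg8_delta_transcription")) {
  rec <- dr_recovery(preset, seed = seed)
  est <- rec$fit_treated$estimate
  message(sprintf("%-24s Emax change %+7.1f%%, EC50 change %+6.1f%% (Emax call: %s)",
                  preset, rec$emax_change_pct, -rec$ec50_change_pct,
                  rec$emax_call))
  rows[[preset]] <- data.frame(
    preset = preset,
    emax_change_pct = rec$emax_change_pct,
    ec50_change_pct = rec$ec50_change_pct,
    emax_call = rec$emax_call, ec50_call = rec$ec50_call,
    b = est["b"], emax = est["emax"], ec50_uM = est["ec50"],
    hill_n = est["hill_n"], row.names = NULL
  )
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/dose_response_fits.csv", row.names = FALSE)
message("wrote results/dose_response_fits.csv")
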