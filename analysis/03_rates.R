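# Unit QC, ISI statistics, adaptive-kernel firing rates, and cue/sipper
# modulation indices.

source("analysis/00_common.R")

cfg <- twocap_config()
rows <- list()
for (i in seq_len(nrow(cohort))) {
  row <- cohort[i, ]
  s <- get_session(row)
  sp <- qc_filter(s$spikes)
  classes <- vapply(sp$units, `[[`, "", "truth_class")
  mi_cue <- modulation_index(sp, s$schedule, "cue_on")
  mi_sip <- modulation_index(sp, s$schedule, "sipper_in")
  sig <- vapply(sp$units, function(u) {
    st <- isi_stats(u$spike_times)
    kernel_sigma(st, cfg$sigma_max_s)
  }, 0)
  rows[[i]] <- data.frame(
    row[, c("id", "strain", "session_type")],
    unit_id = vapply(sp$units, `[[`, "", "unit_id"),
    truth_class = classes, kernel_sigma_s = sig,
    cue_index = mi_cue$units$index, cue_sig = mi_cue$units$significant,
    sip_index = mi_sip$units$index, sip_sig = mi_sip$units$significant)
}
units <- do.call(rbind, rows)
num <- vapply(units, is.numeric, TRUE)
units[num] <- lapply(units[num], round, digits = 4)
write.csv(units, "results/03_unit_modulation.csv", row.names = FALSE)

cat("Units passing QC:", nrow(units), "\n")
cat("Kernel sigma (s) quartiles:\n")
print(quantile(units$kernel_sigma_s, c(0.25, 0.5, 0.75)))
cat("\nProportion significantly cue-modulated by true class:\n")
print(aggregate(cue_sig ~ truth_class, units, mean))
cat("\nProportion significantly sipper-modulated by true class:\n")
print(aggregate(sip_sig ~ truth_class, units, mean))
cat("\nCue-tuned units should dominate the cue index and sipper-tuned",
    "units the sipper index; untuned units sit near the false-positive",
    "rate.\n")
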