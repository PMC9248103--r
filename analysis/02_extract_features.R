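#!/usr/bin/env Rscript
# Extract the four acoustic parameters from the simulated WAV recordings:
# A1 zero-crossing rate, A2 peak/valley amplitude variation, A3 F1/F2
# formant variation (LPC), A4 spectral energy ratio above 3 kHz.
# Writes results/features.csv.

library(frailvoice)

audio_dir <- "results/simulated_cohort/audio"
if (!dir.exists(audio_dir)) stop("run analysis/01_simulate_cohort.R first")

features <- extract_features_batch(audio_dir)
write.csv(features, "results/features.csv", row.names = FALSE)

ok <- features$a1_ok & features$a2_ok & features$a3_ok & features$a4_ok
cat(nrow(features), "recordings;", sum(!ok), "with missing features\n")
for (f in c("a1", "a2", "a3", "a4")) {
  v <- features[[f]]
  cat(sprintf("  %s: mean %.4g, sd %.4g\n", f,
              mean(v, na.rm = TRUE), sd(v, na.rm = TRUE)))
}
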