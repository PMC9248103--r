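#!/usr/bin/env Rscript
# Estimate the acoustic-feature/frailty associations: per-feature ANOVA
# screen, univariate logistic odds ratios on the reporting scales (A1 per
# 1, A2 per 0.1, A3 per 10 Hz, A4 per 0.1) overall and stratified by sex,
# and frailty-probability curves. Writes results/anova.csv,
# results/associations.csv and results/curves.csv.

library(frailvoice)

features <- read.csv("results/features.csv")
assessments <- read.csv("results/assessments.csv")

anova_tab <- anova_table(features, assessments)
write.csv(anova_tab, "results/anova.csv", row.names = FALSE)
cat("ANOVA screen (p < 0.05):",
    paste(with(anova_tab[anova_tab$p_value < 0.05, ],
               paste0(feature, "(", index, ")")), collapse = " "), "\n")

associations <- stratified_associations(features, assessments)
write.csv(associations, "results/associations.csv", row.names = FALSE)

all_rows <- associations[associations$stratum == "all" &
                           associations$estimable, ]
cat("\nall-participant odds ratios (per reporting unit):\n")
for (i in seq_len(nrow(all_rows))) {
  r <- all_rows[i, ]
  cat(sprintf("  %s ~ %-5s OR %.3f (95%% CI %.3f-%.3f)%s\n",
              toupper(r$feature), r$index, r$or_scaled, r$ci_lo, r$ci_hi,
              ifelse(r$p_value < 0.05, " *", "")))
}

curves <- probability_curves_for(associations, features)
write.csv(curves, "results/curves.csv", row.names = FALSE)
cat("\nprobability curves:", nrow(curves), "points ->",
    "results/curves.csv\n")
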