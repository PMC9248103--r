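#!/usr/bin/env Rscript
# Score every participant on the CHS (Fried phenotype), SOF and FRAIL
# indices and build the descriptive frail vs robust/pre-frail comparison
# table. Writes results/assessments.csv and results/descriptives.csv.

library(frailvoice)

participants <- read.csv("results/simulated_cohort/cohort.csv")
assessments <- score_all(participants)
write.csv(assessments, "results/assessments.csv", row.names = FALSE)

for (ix in c("CHS", "SOF", "FRAIL")) {
  sub <- assessments[assessments$index == ix, ]
  cat(sprintf("%-5s frail %d (%.1f%%), pre-frail %d, robust %d\n", ix,
              sum(sub$category == "frail"),
              100 * mean(sub$category == "frail"),
              sum(sub$category == "pre-frail"),
              sum(sub$category == "robust")))
}

descriptives <- descriptive_table(participants, assessments)
write.csv(descriptives, "results/descriptives.csv", row.names = FALSE)
cat("descriptive table:", nrow(descriptives), "rows ->",
    "results/descriptives.csv\n")
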