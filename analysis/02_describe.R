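#!/usr/bin/env Rscript
# Descriptive change analysis: per-item endorsement in each wave, McNemar's
# paired test of marginal change, and scale reliability (KR-20 / alpha).
# Requires results/simulated_panel.csv from 01_simulate.R.

library(symptomnet)

rd <- read_panel_csv("results/simulated_panel.csv")
w1 <- binary_symptoms(rd$panel$wave1_raw, cesd10_labels(), "wave1")
w2 <- binary_symptoms(rd$panel$wave2_raw, cesd10_labels(), "wave2")

tab <- paired_change_table(w1, w2)
tab$wave1_pct <- round(tab$wave1_pct, 2)
tab$wave2_pct <- round(tab$wave2_pct, 2)
tab$chisq <- round(tab$chisq, 3)
write.csv(tab, "results/table_change.csv", row.names = FALSE)

cat(sprintf("n = %d complete cases (%d dropped)\n",
            nrow(w1), rd$n_dropped))
cat(sprintf("Cronbach alpha: wave 1 = %.3f, wave 2 = %.3f\n",
            cronbach_alpha(w1), cronbach_alpha(w2)))
sig <- tab$item[tab$sig != ""]
cat("Items with significant marginal change:\n")
if (length(sig)) cat(paste(" -", sig), sep = "\n") else cat("  none\n")
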