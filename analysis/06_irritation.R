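#!/usr/bin/env Rscript
# Stage 6 — Draize primary irritation index for every treatment group.
#
# Scores the packaged erythema/edema grid (4 timepoints per group):
# PII = sum of all scores / (2 * timepoints), banded into the conventional
# irritation classes.  The 5% SLS positive control scores ~0.66 ("slight");
# every proniosome group scores 0 ("no irritation").

library(pronioptim)
dir.create("results", showWarnings = FALSE)

tab <- draize_pii_table(flp_draize())
print(tab, row.names = FALSE)
write.csv(tab, "results/draize_pii.csv", row.names = FALSE, quote = TRUE)

ee_dl <- data.frame(
  quantity = c("entrapment_efficiency_pct", "drug_loading_pct"),
  example = c(entrapment_efficiency(total_drug = 10, free_drug = 2),
              drug_loading(total_drug = 6, free_drug = 1, total_lipid = 20)))
cat("\nAssay formula spot-checks (EE of 10/2, DL of 6/1/20):\n")
print(ee_dl, row.names = FALSE)
cat("Wrote results/draize_pii.csv\n")
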