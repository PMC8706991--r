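#!/usr/bin/env Rscript
# Stage 1 — construct the rotatable central composite design.
#
# Three formulation factors (finasteride mM, total lipid mM, cholesterol %
# of total lipid), 2^3 factorial + 6 axial + 6 center runs = 20 runs,
# axial distance alpha = (2^3)^(1/4) = 1.682.  Verifies that the generated
# settings coincide with the packaged 20-run study fixture.

library(pronioptim)
dir.create("results", showWarnings = FALSE)

factors <- flp_factors()
design <- ccd_design(factors, n_center = 6, alpha = "rotatable")
cat(sprintf("Built %d-run CCD, alpha = %.4f\n", nrow(design),
            attr(design, "alpha")))

a <- attr(design, "alpha")
for (f in factors)
  cat(sprintf("  %-28s levels: %s %s\n", f$label,
              paste(sprintf("%.2f", coded_to_actual(c(-a, -1, 0, 1, a), f)),
                    collapse = " / "), f$unit))

fix <- flp_design()
key <- function(d) sort(unique(apply(
  round(d[, c("fn_mM", "lipid_mM", "chol_pct")], 2), 1, paste,
  collapse = "/")))
stopifnot(identical(key(as.data.frame(design)), key(as.data.frame(fix))))
cat("Generated settings match the fixture's 15 distinct design points.\n")

write_design_csv(design, "results/ccd_design.csv")
cat("Wrote results/ccd_design.csv\n")
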