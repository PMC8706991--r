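#!/usr/bin/env Rscript
# Stage 3 — multi-response desirability optimization.
#
# Goals: minimize vesicle size, maximize entrapment efficiency, maximize
# drug loading; acceptability bounds set to each response's observed range
# over the 20 runs; search over the coded factorial cube [-1, 1]^3 by
# 0.02-step grid search with local polish.

library(pronioptim)
dir.create("results", showWarnings = FALSE)

design <- flp_design()
models <- list(fit_quadratic(design, "size_nm"),
               fit_quadratic(design, "ee_pct"),
               fit_quadratic(design, "dl_pct"))
goals <- goals_from_ranges(design, c(size_nm = "minimize",
                                     ee_pct = "maximize",
                                     dl_pct = "maximize"))
opt <- optimize_desirability(models, goals)
print(opt)

out <- data.frame(factor = names(opt$actual),
                  coded = opt$coded, actual = opt$actual)
write.csv(format(out, digits = 6), "results/optimum.csv",
          row.names = FALSE, quote = FALSE)
cat(sprintf("\nOptimal formulation: %.2f mM finasteride, %.2f mM total lipid, %.1f%% cholesterol (overall D = %.3f)\n",
            opt$actual["fn_mM"], opt$actual["lipid_mM"],
            opt$actual["chol_pct"], opt$overall_D))
cat("Wrote results/optimum.csv\n")
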