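#!/usr/bin/env Rscript
# Step 5: qRT-PCR validation of two differentially transcribed genes.
#
# Simulates crossing-point tables (3 biological x 2 technical replicates,
# 0.15-cycle biological noise) for two genes with true stress inductions of
# 5- and 2.5-fold in the WT and no change in the deregulated mutant, then
# reduces them to relative amounts with propagated uncertainty.

suppressMessages(library(scostress))

seed <- 42L
wt <- simulate_cp(c(SCO1847 = 5, SCO4498 = 2.5), noise_sd = 0.15,
                  strain = "WT", seed = seed)
mut <- simulate_cp(c(SCO1847 = 1, SCO4498 = 1), noise_sd = 0.15,
                   strain = "mutant", seed = seed + 1L)
out <- qpcr_relative_amounts(rbind(wt, mut))
write_table(out, "results/qpcr_relative_amounts.tsv")

cat("relative transcript amounts (stressed vs unstressed), with propagated sd:\n")
print(out[, .(gene_id, strain, delta_cp = round(delta_cp, 2),
              sd_delta = round(sd_delta, 2),
              rel_amount = round(rel_amount, 2))])
cat("\ntrue folds: SCO1847 5.0, SCO4498 2.5 in WT; 1.0 in the mutant.\n")
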