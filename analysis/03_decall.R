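#!/usr/bin/env Rscript
# Step 3: differential-transcription calling, stressed vs unstressed,
# separately per strain.
#
# Per gene: A = mean log2 RPKM, M = log2 RPKM ratio.  Genes pass the
# expression filter when one condition mean RPKM >= 30 and A > 2; the
# minimal M cutoff is self-calibrated as 2.58 x STDEV of the filter-passing
# M-values (floored at the reporting bound 1.5, i.e. fold changes 2.8/0.4).
# Writes DE tables and MA-plot tables, and checks recovery against the
# planted truth.

suppressMessages(library(scostress))

manifest <- data.table::fread("results/sample_manifest.tsv")
ann <- read_annotation("scratch/simdata/genome.gff3")
truth <- data.table::fread("results/truth_expression.tsv")

for (strain in c("WT", "mutant")) {
  res <- run_strain_contrast(manifest, ann, strain)
  write_table(res$results, sprintf("results/de_%s.tsv", strain))
  data.table::fwrite(ma_plot_table(res$results),
                     sprintf("results/ma_plot_%s.tsv", strain))

  cat("\n==", strain, "stressed vs unstressed ==\n")
  cat(sprintf("STDEV(M) = %.3f -> minimal cutoff m = 2.58 x STDEV = %.2f, effective %.2f\n",
              res$calibration$stdev_m, res$calibration$m_min,
              res$calibration$m_effective))
  print(table(res$results$category))

  m <- merge(res$results, truth, by = "gene_id")
  planted <- m[log2fc != 0]
  pass <- planted[category != "filtered"]
  correct <- pass[(log2fc > 0 & category == "up") |
                    (log2fc < 0 & category == "down")]
  cat(sprintf("planted genes passing filters: %d/%d; called in the correct direction: %d (%.1f%%)\n",
              nrow(pass), nrow(planted), nrow(correct),
              100 * nrow(correct) / max(1, nrow(pass))))
  nulls <- m[log2fc == 0]
  cat(sprintf("false positives among %d null genes: %d (%.2f%%)\n",
              nrow(nulls), sum(nulls$category %in% c("up", "down")),
              100 * mean(nulls$category %in% c("up", "down"))))
}
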