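#!/usr/bin/env Rscript
# Step 1: generate the synthetic study world with known ground truth.
#
# 2 strains (WT, regulator-deletion mutant) x 2 conditions (unstressed,
# H2O2-stressed) x 2 biological replicates of stranded paired-end mapped
# reads over a toy 72%-GC genome; 30 genes planted up and 30 down at
# |log2FC| = 3 in the stressed WT, the mutant fully deregulated.
#
# Large read files go to scratch/simdata/ (not a deliverable); small truth
# tables and the sample manifest go to results/.

suppressMessages(library(scostress))

seed <- 42L
cfg <- sim_config(seed = seed)
dir.create("results", showWarnings = FALSE)
dir.create("scratch/simdata", showWarnings = FALSE, recursive = TRUE)

message("simulating genome (", cfg$n_genes, " CDSs, GC ", cfg$gc_content, ")")
sim <- simulate_genome(cfg)
write_genome(sim, "scratch/simdata/genome.fasta", "scratch/simdata/genome.gff3")

message("simulating ", cfg$fragments_per_sample, " fragments per library")
manifest <- simulate_reads(cfg, sim, "scratch/simdata")

data.table::fwrite(sim$truth, "results/truth_expression.tsv", sep = "\t")
data.table::fwrite(manifest, "results/sample_manifest.tsv", sep = "\t")

pm <- plant_motifs(cfg)
writeLines(paste0(">", names(pm$regions), "\n", pm$regions),
           "scratch/simdata/upstream.fasta")
data.table::fwrite(pm$truth, "results/truth_motifs.tsv", sep = "\t")

cat("genome length:", nchar(sim$genome_seq), "bp;",
    nrow(sim$annotation), "CDSs\n")
cat("libraries:", nrow(manifest), "SAM files under scratch/simdata/\n")
cat("planted DE genes:", sum(sim$truth$log2fc > 0), "up,",
    sum(sim$truth$log2fc < 0), "down at |log2FC| =", cfg$log2fc, "\n")
cat("planted operator sites:", nrow(pm$truth), "regions (see results/truth_motifs.tsv)\n")
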