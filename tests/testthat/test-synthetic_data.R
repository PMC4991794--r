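small_cfg <- function(seed = 7) {
  sim_config(seed = seed, n_genes = 40L, n_up = 4L, n_down = 4L,
             fragments_per_sample = 8000L)
}

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_cfg()
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome_seq, s2$genome_seq)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth, s2$truth)

  d1 <- tempfile(); d2 <- tempfile()
  m1 <- simulate_reads(cfg, s1, d1)
  m2 <- simulate_reads(cfg, s2, d2)
  expect_identical(readLines(m1$reads_path[1]), readLines(m2$reads_path[1]))
})

test_that("simulated CDSs never overlap and respect the length range", {
  sim <- simulate_genome(small_cfg())
  ann <- sim$annotation
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  expect_true(all(ann$length_bp >= 300 & ann$length_bp <= 3000))
  expect_equal(nrow(sim$truth), nrow(ann))
  expect_equal(sum(sim$truth$log2fc > 0), 4L)
  expect_equal(sum(sim$truth$log2fc < 0), 4L)
})

test_that("genome GC content tracks the configured fraction", {
  sim <- simulate_genome(sim_config(seed = 7, n_genes = 80L, n_up = 4L,
                                    n_down = 4L))
  gc <- sum(strsplit(sim$genome_seq, "")[[1]] %in% c("G", "C")) /
    nchar(sim$genome_seq)
  expect_gt(nchar(sim$genome_seq), 1e5)
  expect_equal(gc, 0.72, tolerance = 0.015)   # binomial bound at >=100 kb
})

test_that("genome FASTA/GFF3 written to disk round-trip through the readers", {
  sim <- simulate_genome(small_cfg())
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  write_genome(sim, fa, gff)
  back <- read_annotation(gff)
  expect_equal(back$start, sim$annotation$start)
  expect_equal(back$end, sim$annotation$end)
  expect_equal(back$gene_id, sim$annotation$gene_id)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs[[1]]), sim$genome_seq)
})

test_that("with no orphans and no wide pairs the loop closes: only proper pairs", {
  cfg <- sim_config(seed = 9, n_genes = 30L, n_up = 3L, n_down = 3L,
                    fragments_per_sample = 5000L,
                    orphan_rate = 0, wide_pair_rate = 0)
  sim <- simulate_genome(cfg)
  mf <- simulate_reads(cfg, sim, tempfile())
  rd <- read_mapped_reads(mf$reads_path[1])
  out <- assemble_fragments(rd)
  expect_equal(out$stats$discarded, 0L)
  expect_equal(out$stats$singles, 0L)
  expect_true(all(out$fragments$origin == "paired"))
})

test_that("fragment counts concentrate near their negative-binomial means", {
  cfg <- sim_config(seed = 10, n_genes = 100L, n_up = 0L, n_down = 0L,
                    baseline_sdlog = 0, nb_dispersion = 1e-8,
                    fragments_per_sample = 50000L,
                    orphan_rate = 0, wide_pair_rate = 0)
  sim <- simulate_genome(cfg)
  mf <- simulate_reads(cfg, sim, tempfile())
  cnt <- count_sample(mf$reads_path[1], sim$annotation)
  # equal weights -> expected 500 per gene; dispersion ~0 -> Poisson 3 sigma
  expect_true(mean(abs(cnt$counts - 500) <= 3 * sqrt(500)) >= 0.99)
})

test_that("planted motif truth agrees with the identity scorer", {
  cfg <- small_cfg()
  pm <- plant_motifs(cfg, plants = data.frame(region = 1:6,
                                              L = c(16, 16, 10, 14, 12, 16),
                                              k = c(0, 1, 1, 3, 2, 3)))
  expect_equal(pm$truth$expected_identity,
               as.integer(c(100, 94, 90, 79, 83, 81)))
  for (i in seq_len(nrow(pm$truth))) {
    tr <- pm$truth[i]
    planted <- substr(pm$regions[[tr$name]], tr$position + 1,
                      tr$position + tr$L)
    expect_gte(ungapped_identity(planted)$reported_identity,
               tr$expected_identity)
  }
  # exact plants are found by the scanner at the recorded location
  tr0 <- pm$truth[k == 0][1]
  hits <- scan_upstream(pm$regions[[tr0$name]], min_identity = 100,
                        len_range = c(16, 16))
  expect_true(tr0$position %in% hits$upstream_position)
})

test_that("target identities convert to mismatch counts, unreachable ones error", {
  cfg <- small_cfg()
  pm <- plant_motifs(cfg, plants = data.frame(region = 1:2, L = c(10, 16),
                                              target_identity = c(90, 81)))
  expect_equal(pm$truth$k, c(1L, 3L))
  expect_error(
    plant_motifs(cfg, plants = data.frame(region = 1, L = 10,
                                          target_identity = 85)),
    "achievable")
})

test_that("noise-free CP simulation recovers folds exactly", {
  tab <- simulate_cp(c(a = 1, b = 5), noise_sd = 0, tech_sd = 0, seed = 3)
  out <- qpcr_relative_amounts(tab)
  expect_equal(out[gene_id == "a", delta_cp], 0)
  expect_equal(out[gene_id == "a", rel_amount], 1)
  expect_equal(out[gene_id == "b", rel_amount], 5)
})
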