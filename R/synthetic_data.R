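# Synthetic-data generator: a toy high-GC genome, stranded paired-end
# mapped reads for 2 strains x 2 conditions x 2 replicates with planted
# differential transcription, upstream regions with planted operator sites,
# and qRT-PCR crossing-point tables.  Everything is deterministic under the
# configured seed, and every generated dataset carries its ground truth.

#' Simulation configuration
#'
#' Defaults state the emulated world: 1000 CDSs on a single high-GC
#' (72% GC, *Streptomyces*-like) replicon, 30 up- and 30 down-regulated
#' genes planted at |log2FC| = 3 in the stressed wild type (the mutant is
#' fully deregulated: log2FC = 0 everywhere), 2 biological replicates per
#' strain/condition with negative-binomial count noise (dispersion 0.01),
#' 200,000 paired-end fragments per sample with 75-bp mates and ~200-bp
#' inserts, 5% orphaned mates and 1% wide (>1 kb) pairs to exercise the
#' single-read and discard rules.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of CDSs (default 1000).
#' @param gene_length_range CDS length range in bp (default `c(300, 3000)`).
#' @param gc_content Genome GC fraction (default 0.72).
#' @param n_up,n_down Planted up-/down-regulated gene counts (default 30).
#' @param log2fc Planted |log2 fold change| (default 3).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression weight (default 0, 1).
#' @param nb_dispersion Negative-binomial dispersion of replicate counts
#'   (`var = mu + d * mu^2`; default 0.01).
#' @param fragments_per_sample Fragments per library (default 200000).
#' @param insert_mean,insert_sd Insert length distribution (default 200, 30).
#' @param orphan_rate Fraction of pairs emitted with one mate only
#'   (default 0.05).
#' @param wide_pair_rate Fraction of pairs emitted with span > 1 kb
#'   (default 0.01).
#' @param read_len Mate length in bp (default 75).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_genes = 1000L,
                       gene_length_range = c(300L, 3000L),
                       gc_content = 0.72, n_up = 30L, n_down = 30L,
                       log2fc = 3.0, baseline_meanlog = 0,
                       baseline_sdlog = 1, nb_dispersion = 0.01,
                       fragments_per_sample = 200000L,
                       insert_mean = 200, insert_sd = 30,
                       orphan_rate = 0.05, wide_pair_rate = 0.01,
                       read_len = 75L) {
  stopifnot(n_up + n_down <= n_genes,
            orphan_rate >= 0, orphan_rate <= 1,
            wide_pair_rate >= 0, wide_pair_rate <= 1,
            gc_content >= 0, gc_content <= 1)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a toy genome with non-overlapping CDSs and a truth table
#'
#' CDSs are laid out left to right with random intergenic gaps (100-400 bp)
#' and random strands on a single replicon; `n_up` genes get planted
#' `+log2fc`, `n_down` get `-log2fc`, the rest 0.  Baseline expression
#' weights are log-normal.
#'
#' @param config A [sim_config()].
#' @return List: `genome_seq` (character), `ref_id`, `annotation`
#'   (`data.table` as from [read_annotation()]), `truth` (`data.table`:
#'   `gene_id`, `baseline_weight`, `log2fc`).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  lens <- sample(config$gene_length_range[1L]:config$gene_length_range[2L],
                 n, replace = TRUE)
  gaps <- sample(100:400, n, replace = TRUE)
  flank <- 2000L
  starts <- flank + cumsum(c(0L, lens[-n] + gaps[-n]))
  ends <- starts + lens
  genome_len <- ends[n] + flank
  ann <- data.table(
    gene_id = sprintf("GENE%04d", seq_len(n)),
    ref_id = "synth_chr",
    start = as.integer(starts), end = as.integer(ends),
    strand = sample(c("+", "-"), n, replace = TRUE),
    length_bp = as.integer(lens))
  de_idx <- sample(n, config$n_up + config$n_down)
  lfc <- numeric(n)
  lfc[de_idx[seq_len(config$n_up)]] <- config$log2fc
  lfc[de_idx[config$n_up + seq_len(config$n_down)]] <- -config$log2fc
  truth <- data.table(
    gene_id = ann$gene_id,
    baseline_weight = rlnorm(n, config$baseline_meanlog,
                             config$baseline_sdlog),
    log2fc = lfc)
  list(genome_seq = random_dna(genome_len, config$gc_content),
       ref_id = "synth_chr", annotation = ann, truth = truth)
}

#' Write a simulated genome as FASTA + GFF3
#'
#' @param sim From [simulate_genome()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(sim, fasta_path, gff_path) {
  dna <- Biostrings::DNAStringSet(sim$genome_seq)
  names(dna) <- sim$ref_id
  Biostrings::writeXStringSet(dna, fasta_path)
  ann <- sim$annotation
  gff <- data.table(seqid = ann$ref_id, source = "scostress", type = "CDS",
                    start = ann$start + 1L, end = ann$end, score = ".",
                    strand = ann$strand, phase = "0",
                    attributes = paste0("ID=", ann$gene_id))
  writeLines("##gff-version 3", gff_path)
  fwrite(gff, gff_path, sep = "\t", append = TRUE, col.names = FALSE,
         quote = FALSE)
  invisible(c(fasta_path, gff_path))
}

#' The standard 8-sample design
#'
#' 2 strains (WT, mutant) x 2 conditions (unstressed, stressed) x 2
#' biological replicates.
#'
#' @return `data.table` with `sample_id`, `strain`, `condition`,
#'   `replicate`.
#' @export
sample_manifest <- function() {
  d <- CJ(strain = c("WT", "mutant"), condition = c("unstressed", "stressed"),
          replicate = 1:2)
  d[, sample_id := paste(strain, condition, replicate, sep = "_")]
  setcolorder(d, c("sample_id", "strain", "condition", "replicate"))
  d[]
}

# Per-sample fragment table (genomic mate intervals) for one library.
# Planted log2fc acts only in the stressed wild type; the mutant is fully
# deregulated (log2fc = 0 for every gene).
simulate_sample_fragments <- function(config, sim, strain, condition) {
  ann <- sim$annotation; truth <- sim$truth
  w <- truth$baseline_weight
  if (strain == "WT" && condition == "stressed") w <- w * 2^truth$log2fc
  mu <- config$fragments_per_sample * w / sum(w)
  counts <- rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  gi <- rep(seq_len(nrow(ann)), counts)
  nfrag <- length(gi)
  if (nfrag == 0L) stop("no fragments simulated")
  glen <- ann$length_bp[gi]; gstart <- ann$start[gi]
  rl <- config$read_len
  genome_len <- nchar(sim$genome_seq)

  insert <- round(rnorm(nfrag, config$insert_mean, config$insert_sd))
  insert <- pmax(insert, rl)
  trunc_n <- sum(insert > glen)
  insert <- pmin(insert, glen)
  if (trunc_n > 0L) {
    warning(trunc_n, " insert(s) longer than their gene truncated")
  }
  wide <- runif(nfrag) < config$wide_pair_rate
  insert[wide] <- sample(1001:1500, sum(wide), replace = TRUE)

  fs <- gstart + floor(runif(nfrag) * pmax(1, glen - insert + 1))
  fs <- pmin(fs, genome_len - insert)   # wide pairs may leave the gene
  fe <- fs + insert

  gstrand <- ann$strand[gi]
  # forward-library orientation: first mate on the transcript strand
  m1_start <- fifelse(gstrand == "+", fs, fe - rl)
  m2_start <- fifelse(gstrand == "+", fe - rl, fs)
  m1_strand <- gstrand
  m2_strand <- fifelse(gstrand == "+", "-", "+")

  orphan <- runif(nfrag) < config$orphan_rate
  drop_first <- orphan & (runif(nfrag) < 0.5)   # which mate goes missing
  data.table(
    frag_id = seq_len(nfrag), gene_idx = gi,
    m1_start = as.integer(m1_start), m1_strand = m1_strand,
    m2_start = as.integer(m2_start), m2_strand = m2_strand,
    wide = wide, emit_first = !(orphan & drop_first),
    emit_second = !(orphan & !drop_first))
}

#' Simulate mapped paired-end reads for the full design
#'
#' Per-gene fragment counts are negative-binomial with condition-specific
#' means (`baseline * 2^log2fc` in the stressed wild type; the mutant is
#' deregulated).  Fragments are placed uniformly within their CDS; mate
#' intervals follow the insert length; `orphan_rate` of pairs lose one mate
#' and `wide_pair_rate` get a span > 1 kb so downstream discard rules are
#' exercised.  Reads are written as minimal SAM, one file per sample.
#'
#' @param config A [sim_config()].
#' @param sim From [simulate_genome()].
#' @param out_dir Directory for the SAM files (created if needed).
#' @param manifest Sample sheet (default [sample_manifest()]).
#' @return The manifest with a `reads_path` column appended.
#' @export
simulate_reads <- function(config, sim, out_dir,
                           manifest = sample_manifest()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  rl <- config$read_len
  genome_len <- nchar(sim$genome_seq)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    mf <- manifest[i]
    fr <- suppressWarnings(
      simulate_sample_fragments(config, sim, mf$strain, mf$condition))
    fr[, qname := paste0(mf$sample_id, ":frag", frag_id)]
    fr[, flag1 := 1L + 64L + fifelse(m1_strand == "-", 16L, 0L) +
         fifelse(m2_strand == "-", 32L, 0L)]
    fr[, flag2 := 1L + 128L + fifelse(m2_strand == "-", 16L, 0L) +
         fifelse(m1_strand == "-", 32L, 0L)]
    sam1 <- fr[emit_first == TRUE,
               .(q = qname, f = flag1,
                 r = sim$ref_id, p = m1_start + 1L, mq = 255L,
                 cg = paste0(rl, "M"), rn = "*", pn = 0L, tl = 0L,
                 sq = "*", ql = "*")]
    sam2 <- fr[emit_second == TRUE,
               .(q = qname, f = flag2,
                 r = sim$ref_id, p = m2_start + 1L, mq = 255L,
                 cg = paste0(rl, "M"), rn = "*", pn = 0L, tl = 0L,
                 sq = "*", ql = "*")]
    sam <- rbindlist(list(sam1, sam2))
    setorder(sam, p)
    path <- file.path(out_dir, paste0(mf$sample_id, ".sam"))
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 paste0("@SQ\tSN:", sim$ref_id, "\tLN:", genome_len)), path)
    fwrite(sam, path, sep = "\t", append = TRUE, col.names = FALSE,
           quote = FALSE)
    paths[i] <- path
  }
  out <- copy(manifest)
  out[, reads_path := paths]
  out[]
}

#' Plant degenerate operator sites in synthetic upstream regions
#'
#' Generates fixed-length upstream regions at genome GC and plants, in a
#' chosen subset, a copy of the reference site's first `L` bases carrying
#' exactly `k` substitutions, so the expected reported identity is
#' `round(100 * (L - k) / L)`.
#'
#' @param config A [sim_config()] (supplies seed and GC).
#' @param reference Reference site (default [REFERENCE_SITE]).
#' @param n_regions Number of upstream regions (default 30).
#' @param region_length Region length in bp (default 200).
#' @param plants `data.table`/`data.frame` with columns `region` (1-based
#'   index), `L` (planted length), and either `k` (mismatch count) or
#'   `target_identity` (integer percent; converted to `k`, error if no `k`
#'   gives that rounded identity).  Default: regions `1:10` with `L` 16 and
#'   `k` cycling 0-3.
#' @return List: `regions` (named character vector of sequences), `truth`
#'   (`data.table`: `name`, `position` 0-based, `L`, `k`,
#'   `expected_identity`, `distance_to_start`).
#' @export
plant_motifs <- function(config = sim_config(), reference = REFERENCE_SITE,
                         n_regions = 30L, region_length = 200L,
                         plants = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(plants)) {
    plants <- data.table(region = 1:10, L = 16L, k = rep(0:3, length.out = 10))
  }
  plants <- as.data.table(plants)
  if (!"k" %in% names(plants)) {
    plants[, k := {
      kk <- vapply(seq_len(.N), function(i) {
        cand <- 0:L[i]
        hit <- cand[round_half_up(100 * (L[i] - cand) / L[i]) ==
                      target_identity[i]]
        if (length(hit) == 0L) {
          stop("identity ", target_identity[i], " unreachable for L = ",
               L[i], "; achievable: ",
               paste(unique(round_half_up(100 * (L[i] - 0:L[i]) / L[i])),
                     collapse = ", "))
        }
        hit[1L]
      }, integer(1L))
      kk
    }]
  }
  stopifnot(all(plants$L <= nchar(reference)), all(plants$k <= plants$L))

  regions <- vapply(seq_len(n_regions),
                    function(i) random_dna(region_length, config$gc_content),
                    character(1L))
  names(regions) <- sprintf("UPSTREAM%03d", seq_len(n_regions))
  bases <- c("A", "C", "G", "T")
  truth <- plants[, {
    site <- strsplit(substr(reference, 1L, L), "", fixed = TRUE)[[1L]]
    if (k > 0L) {
      pos_mut <- sample(L, k)
      site[pos_mut] <- vapply(site[pos_mut],
                              function(b) sample(setdiff(bases, b), 1L),
                              character(1L))
    }
    pos <- sample.int(region_length - L + 1L, 1L) - 1L   # 0-based
    seqstr <- regions[[region]]
    substr(seqstr, pos + 1L, pos + L) <- paste(site, collapse = "")
    regions[[region]] <<- seqstr
    .(name = names(regions)[region], position = pos,
      expected_identity = as.integer(round_half_up(100 * (L - k) / L)),
      distance_to_start = region_length - (pos + L))
  }, by = .(region, L, k)]
  list(regions = regions,
       truth = truth[, .(name, position, L, k, expected_identity,
                         distance_to_start)])
}

#' Simulate a qRT-PCR crossing-point table
#'
#' CP values are `base_cp` in the reference condition and
#' `base_cp - log2(fold)` in the treatment, plus per-biological-replicate
#' Gaussian noise (`noise_sd`) and smaller technical noise (`tech_sd`).
#'
#' @param true_folds Named positive vector: true relative amount
#'   (treatment vs reference) per gene.
#' @param noise_sd Biological CP noise in cycles (default 0.15).
#' @param tech_sd Technical CP noise (default 0.05).
#' @param n_bio,n_tech Replicate design (default 3 x 2).
#' @param base_cp Reference-condition mean CP (default 20).
#' @param strain Strain label for the output (default `"WT"`).
#' @param seed Optional seed (set if not `NULL`).
#' @return `data.table`: `gene_id`, `strain`, `condition`, `bio_rep`,
#'   `tech_rep`, `cp`.
#' @export
simulate_cp <- function(true_folds, noise_sd = 0.15, tech_sd = 0.05,
                        n_bio = 3L, n_tech = 2L, base_cp = 20,
                        strain = "WT", seed = NULL) {
  stopifnot(all(true_folds > 0))
  if (!is.null(seed)) set.seed(seed)
  grid <- CJ(gene_id = names(true_folds),
             condition = c("unstressed", "stressed"),
             bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech))
  # one biological noise draw per (gene, condition, bio_rep)
  bio <- grid[tech_rep == 1L, .(gene_id, condition, bio_rep)]
  bio[, bio_noise := rnorm(.N, 0, noise_sd)]
  grid <- bio[grid, on = .(gene_id, condition, bio_rep)]
  grid[, cp := base_cp -
         fifelse(condition == "stressed", log2(true_folds[gene_id]), 0) +
         bio_noise + rnorm(.N, 0, tech_sd)]
  grid[, strain := strain]
  grid[, bio_noise := NULL]
  setcolorder(grid, c("gene_id", "strain", "condition", "bio_rep",
                      "tech_rep", "cp"))
  grid[]
}
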