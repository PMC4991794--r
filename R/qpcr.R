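# qRT-PCR crossing-point (CP) reduction.  CPs are averaged in two stages --
# technical replicates first, then biological replicates -- and the
# uncertainty of a CP difference is propagated in quadrature assuming
# non-correlated errors.  No reference-gene normalisation: the assay design
# compares CPs directly on fixed RNA input, with amplification efficiency
# fixed at 2 per cycle.

#' Two-stage CP summary for one gene/strain/condition
#'
#' @param cp Numeric crossing points (cycles).
#' @param bio_rep Biological replicate index per reading.
#' @param tech_rep Technical replicate index per reading (unused beyond
#'   validation; technical readings are averaged within each `bio_rep`).
#' @return List `mean_cp` (unweighted mean of the biological-replicate
#'   means), `sd` (sample standard deviation across biological-replicate
#'   means; `NA` with < 2 of them), `n_bio`.
#' @examples
#' # tech pairs (20.0, 20.2), (19.9, 20.1), (20.3, 20.5):
#' summarize_cp(c(20, 20.2, 19.9, 20.1, 20.3, 20.5),
#'              bio_rep = c(1, 1, 2, 2, 3, 3))$mean_cp  # 20.1667
#' @export
summarize_cp <- function(cp, bio_rep, tech_rep = NULL) {
  stopifnot(length(cp) == length(bio_rep), all(cp > 0))
  bio_means <- tapply(cp, bio_rep, mean)
  n_bio <- length(bio_means)
  if (n_bio < 2L) {
    if (n_bio < 1L) stop("no biological replicates")
    warning("single biological replicate: sd unavailable")
  }
  list(mean_cp = mean(bio_means),
       sd = if (n_bio >= 2L) stats::sd(bio_means) else NA_real_,
       n_bio = n_bio)
}

#' Relative transcript amount between two conditions
#'
#' `delta_cp = mean_cp_b - mean_cp_a`; a lower CP means more template, so
#' the relative amount of condition *b* versus *a* is
#' `rel_amount = efficiency^(-delta_cp)`.  The standard deviation of the
#' difference is the quadrature sum `sqrt(sd_a^2 + sd_b^2)` (non-correlated
#' errors).
#'
#' @param summary_a,summary_b Summaries from [summarize_cp()]; *a* is the
#'   reference condition.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return List `delta_cp`, `sd_delta`, `rel_amount`, plus the input means
#'   and sds.
#' @examples
#' a <- list(mean_cp = 20.0, sd = 0.3)
#' b <- list(mean_cp = 17.68, sd = 0.4)
#' relative_amount(a, b)$rel_amount  # ~4.99 (2^2.32)
#' relative_amount(a, b)$sd_delta    # 0.5
#' @export
relative_amount <- function(summary_a, summary_b, efficiency = 2) {
  delta <- summary_b$mean_cp - summary_a$mean_cp
  sd_delta <- sqrt(summary_a$sd^2 + summary_b$sd^2)
  list(mean_cp_a = summary_a$mean_cp, mean_cp_b = summary_b$mean_cp,
       sd_a = summary_a$sd, sd_b = summary_b$sd,
       delta_cp = delta, sd_delta = sd_delta,
       rel_amount = efficiency^(-delta))
}

#' Reduce a CP table to relative amounts per gene and strain
#'
#' Runs [summarize_cp()] per (gene, strain, condition) and
#' [relative_amount()] for the stressed-vs-unstressed contrast within each
#' strain.  The relative amount is reported per strain (stressed relative to
#' the same strain unstressed) and additionally normalised to the unstressed
#' wild type (`rel_amount_vs_wt`).
#'
#' @param cp_table `data.frame`/`data.table` with columns `gene_id`,
#'   `strain`, `condition`, `bio_rep`, `tech_rep`, `cp`.
#' @param ref_condition Reference condition (default `"unstressed"`).
#' @param trt_condition Treatment condition (default `"stressed"`).
#' @param wt_strain Strain used for the cross-strain normalisation
#'   (default `"WT"`).
#' @param efficiency Amplification efficiency (default 2).
#' @return `data.table`, one row per (gene, strain), with mean CPs, ΔCP,
#'   propagated sd and relative amounts.
#' @export
qpcr_relative_amounts <- function(cp_table, ref_condition = "unstressed",
                                  trt_condition = "stressed",
                                  wt_strain = "WT", efficiency = 2) {
  dt <- as.data.table(cp_table)
  need <- c("gene_id", "strain", "condition", "bio_rep", "cp")
  stopifnot(all(need %in% names(dt)))
  sums <- dt[, {
    s <- summarize_cp(cp, bio_rep)
    .(mean_cp = s$mean_cp, sd = s$sd, n_bio = s$n_bio)
  }, by = .(gene_id, strain, condition)]

  out <- sums[condition == ref_condition][
    sums[condition == trt_condition],
    on = .(gene_id, strain), nomatch = NULL]
  out <- out[, {
    ra <- relative_amount(list(mean_cp = mean_cp, sd = sd),
                          list(mean_cp = i.mean_cp, sd = i.sd),
                          efficiency = efficiency)
    .(mean_cp_ref = ra$mean_cp_a, mean_cp_trt = ra$mean_cp_b,
      sd_ref = ra$sd_a, sd_trt = ra$sd_b,
      delta_cp = ra$delta_cp, sd_delta = ra$sd_delta,
      rel_amount = ra$rel_amount)
  }, by = .(gene_id, strain)]

  # normalisation to the unstressed wild type: amount of each sample
  # relative to WT-unstressed of the same gene
  wt_ref <- sums[strain == wt_strain & condition == ref_condition,
                 .(gene_id, wt_ref_cp = mean_cp)]
  out <- wt_ref[out, on = "gene_id"]
  out[, rel_amount_vs_wt := efficiency^(-(mean_cp_trt - wt_ref_cp))]
  out[, wt_ref_cp := NULL]
  out[]
}
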