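# MA-statistic differential transcription calling with a self-calibrated
# minimal M cutoff.  No variance model: the design has two biological
# replicates and the cutoff is derived from the empirical spread of M under
# the assumption that most genes are not differentially transcribed.

#' Default thresholds for differential-transcription calling
#'
#' @param rpkm_min Expression filter: at least one condition mean RPKM must
#'   reach this value (default 30).
#' @param a_min A-value filter, strict (default 2.0).
#' @param m_floor Reporting M cutoff (default 1.5, i.e. fold changes 2.8
#'   and 0.4).
#' @param z_coeff Coefficient on the M standard deviation for the
#'   self-calibrated minimal cutoff (default 2.58, the two-sided 1% normal
#'   quantile: 99% of null M-values fall within the band).
#' @return List of class `de_config`.
#' @export
de_config <- function(rpkm_min = 30, a_min = 2.0, m_floor = 1.5,
                      z_coeff = 2.58) {
  stopifnot(rpkm_min >= 0, a_min >= 0, m_floor >= 0, z_coeff >= 0)
  structure(list(rpkm_min = rpkm_min, a_min = a_min, m_floor = m_floor,
                 z_coeff = z_coeff), class = "de_config")
}

#' M and A statistics for one gene
#'
#' Replicate RPKMs are combined by arithmetic mean per condition, then
#' `M = log2(mean_trt) - log2(mean_ref)` (the signal intensity ratio) and
#' `A = (log2(mean_trt) + log2(mean_ref)) / 2` (the signal intensity).
#'
#' @param rpkm_ref_reps Positive replicate RPKMs in the reference
#'   (unstressed) condition.
#' @param rpkm_trt_reps Positive replicate RPKMs in the treatment (stressed)
#'   condition.
#' @return Named list `M`, `A`, `mean_rpkm_ref`, `mean_rpkm_trt`.
#' @export
ma_statistics <- function(rpkm_ref_reps, rpkm_trt_reps) {
  if (length(rpkm_ref_reps) < 1L || length(rpkm_trt_reps) < 1L) {
    stop("need >= 1 replicate per condition")
  }
  if (any(rpkm_ref_reps <= 0) || any(rpkm_trt_reps <= 0)) {
    stop("non-positive RPKM (impossible after pseudocount)")
  }
  mr <- mean(rpkm_ref_reps); mt <- mean(rpkm_trt_reps)
  list(M = log2(mt) - log2(mr), A = (log2(mt) + log2(mr)) / 2,
       mean_rpkm_ref = mr, mean_rpkm_trt = mt)
}

#' Fold change corresponding to an M-value
#'
#' @param M log2 expression ratio(s).
#' @return `2^M`.  Reported to two decimals in output tables.
#' @examples
#' round(fold_change(3.19), 2)  # 9.13
#' round(fold_change(1.5), 1)   # 2.8
#' @export
fold_change <- function(M) 2^M

#' Self-calibrated minimal M cutoff
#'
#' Under the assumption that most genes are not differentially transcribed,
#' the M distribution is centred and its standard deviation estimates the
#' null spread; `m_min = z_coeff * STDEV` then leaves ~1% of null genes
#' outside `[-m_min, +m_min]` (for `z_coeff = 2.58`).  The effective cutoff
#' never drops below the reporting floor: `m_effective = max(m_floor, m_min)`.
#'
#' @param all_M M-values of all genes passing the expression filter
#'   (>= 2 values).
#' @param config A [de_config()].
#' @return List `stdev_m`, `m_min`, `m_effective`.
#' @export
calibrate_cutoff <- function(all_M, config = de_config()) {
  if (length(all_M) < 2L) stop("need >= 2 M-values to calibrate the cutoff")
  s <- stats::sd(all_M)               # sample (n-1) estimator
  m_min <- config$z_coeff * s
  list(stdev_m = s, m_min = m_min,
       m_effective = max(config$m_floor, m_min))
}

#' Two-condition differential-transcription contrast
#'
#' Runs the whole MA workflow for one contrast: per-gene M/A statistics from
#' replicate RPKM columns, cutoff calibration on filter-passing genes, and
#' classification.  A gene is `filtered` when both condition means fall
#' below `rpkm_min` or its A-value is `<= a_min`; otherwise `up` when
#' `M >= +m_effective`, `down` when `M <= -m_effective`, else `non`.  The
#' categories partition the gene set.
#'
#' @param rpkm_mat Genes x samples matrix of positive RPKMs (as from
#'   [rpkm_matrix()]).
#' @param ref_cols,trt_cols Column names/indices of the reference
#'   (unstressed) and treatment (stressed) replicates.
#' @param config A [de_config()].
#' @return List with `results` (`data.table`: `gene_id`, `mean_rpkm_ref`,
#'   `mean_rpkm_trt`, `A`, `M`, `fold_change`, `category`) and
#'   `calibration` (from [calibrate_cutoff()]).
#' @export
de_contrast <- function(rpkm_mat, ref_cols, trt_cols, config = de_config()) {
  ref <- rpkm_mat[, ref_cols, drop = FALSE]
  trt <- rpkm_mat[, trt_cols, drop = FALSE]
  if (any(ref <= 0) || any(trt <= 0)) stop("non-positive RPKM")
  mr <- rowMeans(ref); mt <- rowMeans(trt)
  M <- log2(mt) - log2(mr)
  A <- (log2(mt) + log2(mr)) / 2
  res <- data.table(gene_id = rownames(rpkm_mat),
                    mean_rpkm_ref = mr, mean_rpkm_trt = mt,
                    A = A, M = M, fold_change = 2^M)
  pass <- pmax(mr, mt) >= config$rpkm_min & A > config$a_min
  if (sum(pass) < 2L) stop("fewer than 2 genes pass the expression filter")
  calibration <- calibrate_cutoff(M[pass], config)
  res[, category := classify(M, pass, calibration, config)]
  list(results = res[], calibration = calibration)
}

#' Classify genes given a calibrated cutoff
#'
#' @param M Per-gene M-values.
#' @param pass Logical: gene passes the expression filter.
#' @param calibration From [calibrate_cutoff()].
#' @param config A [de_config()].
#' @return Character vector over `{up, down, non, filtered}`.
#' @export
classify <- function(M, pass, calibration, config = de_config()) {
  m <- calibration$m_effective
  fifelse(!pass, "filtered",
          fifelse(M >= m, "up", fifelse(M <= -m, "down", "non")))
}

#' MA-plot table
#'
#' One row per non-filtered gene with the conventional colour tag: green for
#' up-regulated, red for down-regulated, grey for non-regulated.
#'
#' @param results The `results` table of a [de_contrast()].
#' @return `data.table` with `gene_id`, `A`, `M`, `category`, `color`.
#' @export
ma_plot_table <- function(results) {
  dt <- as.data.table(results)[category != "filtered"]
  dt[, .(gene_id, A, M, category,
         color = c(up = "green", down = "red", non = "grey")[category])]
}
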