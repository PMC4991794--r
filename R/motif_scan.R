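# Operator-site scanning by ungapped percent identity against a reference
# binding site, plus sequence-logo information content.  The default
# reference is the 16-bp response-regulator operator CCGGGCCGCGTCCCGT
# (binding site III).  Identity is deliberately ungapped: the shorter
# sequence slides along the longer and the best full-overlap offset wins.

#' The default reference operator site
#' @export
REFERENCE_SITE <- "CCGGGCCGCGTCCCGT"

#' Best ungapped percent identity between two sequences
#'
#' Slides the shorter sequence along the longer over all offsets with full
#' overlap; at each offset the identity is the number of positionwise equal
#' characters.  `pct_identity = 100 * max(matches) / len(shorter)`; ties in
#' the maximum are broken by the smallest offset.  Non-ACGT characters never
#' match and count in the length.  The operation is symmetric in its two
#' arguments.
#'
#' @param candidate,reference Non-empty uppercase DNA strings.
#' @return List: `candidate`, `pct_identity` (real, 0-100),
#'   `reported_identity` (integer, round half-up), `best_offset`
#'   (0-based offset of the shorter within the longer).
#' @examples
#' ungapped_identity("CCGGGCCGCT", REFERENCE_SITE)$reported_identity  # 90
#' @export
ungapped_identity <- function(candidate, reference = REFERENCE_SITE) {
  if (nchar(candidate) == 0L || nchar(reference) == 0L) {
    stop("empty sequence")
  }
  a <- strsplit(candidate, "", fixed = TRUE)[[1L]]
  b <- strsplit(reference, "", fixed = TRUE)[[1L]]
  if (length(a) <= length(b)) { short <- a; long <- b } else { short <- b; long <- a }
  ls <- length(short); ll <- length(long)
  valid <- short %in% c("A", "C", "G", "T")
  best <- -1L; best_off <- 0L
  for (off in 0L:(ll - ls)) {
    m <- sum(valid & short == long[(off + 1L):(off + ls)])
    if (m > best) { best <- m; best_off <- off }
  }
  pct <- 100 * best / ls
  list(candidate = candidate, pct_identity = pct,
       reported_identity = as.integer(round_half_up(pct)),
       best_offset = best_off)
}

#' Scan an upstream region for candidate operator sites
#'
#' The upstream sequence must be oriented 5'->3' on the coding strand and
#' end at the base immediately before the start codon.  Every substring with
#' length in `len_range` is scored by [ungapped_identity()]; hits at or above
#' `min_identity` are resolved greedily (best percent identity, then longest,
#' then leftmost) so the returned hits never overlap.
#' `distance_to_start` counts the bases strictly between a site's 3' end and
#' the start codon.
#'
#' @param upstream_seq Character DNA string (coding strand, 5'->3').
#' @param reference Reference site (default [REFERENCE_SITE]).
#' @param len_range Window length range, `c(min, max)` (default `c(10, 20)`).
#' @param min_identity Minimum percent identity to report (default 53).
#' @param revcomp Also scan the reverse complement and report `strand`
#'   (default `FALSE`: forward only).
#' @return `data.table` with columns `candidate`, `pct_identity`,
#'   `reported_identity`, `best_offset`, `upstream_position` (0-based start
#'   within the region), `distance_to_start`, `strand`; zero rows when
#'   nothing reaches `min_identity`.
#' @export
scan_upstream <- function(upstream_seq, reference = REFERENCE_SITE,
                          len_range = c(10, 20), min_identity = 53,
                          revcomp = FALSE) {
  if (len_range[1L] > len_range[2L]) stop("len_range inverted")
  n <- nchar(upstream_seq)
  if (n < len_range[1L]) stop("upstream sequence shorter than min window")

  scan_one <- function(seqstr, strand) {
    hits <- list()
    for (w in len_range[1L]:min(len_range[2L], n)) {
      for (s in 0L:(n - w)) {
        cand <- substr(seqstr, s + 1L, s + w)
        h <- ungapped_identity(cand, reference)
        if (h$pct_identity >= min_identity) {
          hits[[length(hits) + 1L]] <- data.table(
            candidate = cand, pct_identity = h$pct_identity,
            reported_identity = h$reported_identity,
            best_offset = h$best_offset,
            upstream_position = s,
            distance_to_start = n - (s + w),
            strand = strand)
        }
      }
    }
    rbindlist(hits)
  }

  all_hits <- scan_one(upstream_seq, "+")
  if (revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(upstream_seq)))
    rc_hits <- scan_one(rc, "-")
    if (nrow(rc_hits) > 0L) {
      # map coordinates back to the forward strand
      w <- nchar(rc_hits$candidate)
      rc_hits[, upstream_position := n - upstream_position - w]
      rc_hits[, distance_to_start := n - (upstream_position + w)]
    }
    all_hits <- rbindlist(list(all_hits, rc_hits))
  }
  empty <- data.table(candidate = character(), pct_identity = numeric(),
                      reported_identity = integer(), best_offset = integer(),
                      upstream_position = integer(),
                      distance_to_start = integer(), strand = character())
  if (is.null(all_hits) || nrow(all_hits) == 0L) return(empty)

  setorder(all_hits, -pct_identity, candidate, upstream_position)
  all_hits[, len := nchar(candidate)]
  setorderv(all_hits, c("pct_identity", "len", "upstream_position"),
            order = c(-1L, -1L, 1L))
  keep <- logical(nrow(all_hits))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(all_hits))) {
    s <- all_hits$upstream_position[i]; e <- s + all_hits$len[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  out <- all_hits[keep][, len := NULL]
  setorder(out, upstream_position)
  out[]
}

#' Scan a FASTA file of upstream regions
#'
#' @param fasta_path FASTA of upstream regions (coding strand, ending at the
#'   base before the start codon).
#' @param ... Passed to [scan_upstream()].
#' @return `data.table` of hits with a leading `name` column (FASTA record
#'   names).
#' @export
scan_upstream_fasta <- function(fasta_path, ...) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- rbindlist(lapply(seq_along(seqs), function(i) {
    h <- scan_upstream(as.character(seqs[[i]]), ...)
    if (nrow(h) > 0L) h[, name := names(seqs)[i]]
    h
  }), fill = TRUE)
  if (nrow(out) > 0L) setcolorder(out, "name")
  out
}

#' Per-position information content of aligned sites
#'
#' For each column the base frequencies are taken over non-gap characters
#' and the information content is `bits = 2 - H` where `H` is the Shannon
#' entropy in bits; 2 bits means perfect conservation, 0 a uniform column.
#' The optional small-sample correction subtracts `3 / (2 * ln(2) * n)`
#' (n = non-gap count), clipped at 0.
#'
#' @param sites Character vector of >= 2 equal-length aligned sequences;
#'   `-` marks gaps.
#' @param correction Apply the small-sample correction (default `FALSE`).
#' @return `data.table` with `position` (1-based), `bits`, and frequency
#'   columns `A`, `C`, `G`, `T`.
#' @export
information_content <- function(sites, correction = FALSE) {
  if (length(sites) < 2L) stop("need >= 2 sites")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    stop("sites must be equal length (alignment is the caller's job)")
  }
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    n <- length(col)
    f <- table(factor(col, levels = bases)) / n
    f <- as.numeric(f)
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    bits <- 2 - h
    if (correction) bits <- max(0, bits - 3 / (2 * log(2) * n))
    data.table(position = j, bits = bits,
               A = f[1L], C = f[2L], G = f[3L], T = f[4L])
  })
  rbindlist(out)
}
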