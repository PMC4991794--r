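#' @import data.table
#' @importFrom stats rnbinom rnorm rlnorm runif sd setNames
#' @importFrom utils write.table read.table
NULL

# All genomic intervals are 0-based half-open internally.  GFF3 (1-based
# inclusive) is converted at the boundary; BED6 is already 0-based half-open.

#' Read a CDS annotation from GFF3 or BED6
#'
#' Parses the coding-sequence features the pipeline counts against.  GFF3
#' coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; BED6 is taken as-is.  Feature identifiers come from
#' the `ID` or `locus_tag` attribute (GFF3) or the name column (BED).
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.  Format is chosen by
#'   extension unless `format` is given.
#' @param format `"gff3"`, `"bed"` or `NULL` (autodetect from extension).
#' @param feature_types GFF3 `type` values accepted as features
#'   (default `c("CDS", "gene")`).
#' @return A `data.table` with columns `gene_id`, `ref_id`, `start`, `end`
#'   (0-based half-open), `strand`, `length_bp`, sorted by `(ref_id, start)`.
#'   Rows lacking an identifier are dropped with a warning; `end <= start` is
#'   an error naming the offending feature.
#' @export
read_annotation <- function(path, format = NULL,
                            feature_types = c("CDS", "gene")) {
  stopifnot(file.exists(path))
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  format <- match.arg(format, c("gff3", "bed"))

  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% feature_types]
    meta <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
    if ("locus_tag" %in% names(meta)) {
      lt <- as.character(meta$locus_tag)
      ids <- ifelse(is.na(ids) | ids == "", lt, ids)
    }
    drop <- is.na(ids) | ids == ""
    if (any(drop)) {
      warning(sum(drop), " annotation row(s) without ID/locus_tag dropped")
      gr <- gr[!drop]; ids <- ids[!drop]
    }
    ann <- data.table(
      gene_id = ids,
      ref_id  = as.character(GenomicRanges::seqnames(gr)),
      start   = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end     = GenomicRanges::end(gr),
      strand  = as.character(GenomicRanges::strand(gr))
    )
  } else {
    bed <- fread(path, header = FALSE, sep = "\t",
                 col.names = c("ref_id", "start", "end", "gene_id",
                               "score", "strand")[1:6])
    ann <- bed[, .(gene_id = as.character(gene_id),
                   ref_id = as.character(ref_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand))]
  }

  bad <- ann[end <= start]
  if (nrow(bad) > 0L) {
    stop("annotation feature with end <= start: ", bad$gene_id[1L],
         " [", bad$start[1L], ",", bad$end[1L], ")")
  }
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicated gene_id in annotation: ",
         ann$gene_id[duplicated(ann$gene_id)][1L])
  }
  ann[, length_bp := end - start]
  setkey(ann, ref_id, start)
  ann[]
}

# Reference-consuming CIGAR operators: M, D, N, =, X
cigar_reference_span <- function(cigar) {
  # real libraries carry few distinct CIGAR strings; parse each once
  if (length(cigar) > 1000L) {
    u <- unique(cigar)
    if (length(u) < length(cigar) / 2L) {
      return(cigar_reference_span(u)[match(cigar, u)])
    }
  }
  spans <- integer(length(cigar))
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    if (length(o) == 0L) { spans[i] <- NA_integer_; next }
    len <- as.integer(sub("[MIDNSHP=X]$", "", o))
    op  <- sub("^\\d+", "", o)
    spans[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  spans
}

#' Read mapped reads from a minimal SAM subset or a TSV
#'
#' The SAM reader honours only the columns QNAME, FLAG, RNAME, POS, CIGAR and
#' the flag bits 0x1 (paired), 0x4 (unmapped), 0x10 (reverse), 0x40 (first
#' mate), 0x80 (second mate).  The reference end is `POS - 1 +` the sum of
#' reference-consuming CIGAR lengths (M, D, N, =, X).  Unmapped records are
#' skipped; records whose CIGAR consumes no reference are rejected with a
#' warning.  The TSV fallback expects columns
#' `read_id, mate, ref_id, start, end, strand` already in 0-based half-open
#' coordinates.
#'
#' @param path SAM (`.sam`) or TSV file.
#' @param format `"sam"`, `"tsv"` or `NULL` (autodetect from extension).
#' @return `data.table` with columns `read_id`, `mate`
#'   (`first`/`second`/`unpaired`), `ref_id`, `start`, `end`, `strand`.
#' @export
read_mapped_reads <- function(path, format = NULL) {
  stopifnot(file.exists(path))
  if (is.null(format)) {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  format <- match.arg(format, c("sam", "tsv"))

  if (format == "tsv") {
    rd <- fread(path, sep = "\t", header = TRUE)
    need <- c("read_id", "mate", "ref_id", "start", "end", "strand")
    if (!all(need %in% names(rd))) {
      stop("mapped-read TSV must have columns: ", paste(need, collapse = ", "))
    }
    if (!all(rd$mate %in% c("first", "second", "unpaired"))) {
      stop("unknown mate designation in TSV: ",
           paste(unique(setdiff(rd$mate, c("first", "second", "unpaired"))),
                 collapse = ", "))
    }
    return(rd[, .(read_id = as.character(read_id), mate = as.character(mate),
                  ref_id = as.character(ref_id), start = as.integer(start),
                  end = as.integer(end), strand = as.character(strand))])
  }

  lines <- fread(path, sep = "\t", header = FALSE, fill = TRUE,
                 blank.lines.skip = TRUE)
  lines <- lines[!startsWith(V1, "@")]
  if (nrow(lines) == 0L) {
    return(data.table(read_id = character(), mate = character(),
                      ref_id = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  flag <- as.integer(lines$V2)
  keep <- bitwAnd(flag, 4L) == 0L                  # drop unmapped
  lines <- lines[keep]; flag <- flag[keep]
  span <- cigar_reference_span(as.character(lines$V6))
  bad <- is.na(span) | span == 0L
  if (any(bad)) {
    warning(sum(bad), " SAM record(s) with no reference-consuming CIGAR ",
            "operator rejected")
    lines <- lines[!bad]; flag <- flag[!bad]; span <- span[!bad]
  }
  paired <- bitwAnd(flag, 1L) != 0L
  mate <- fifelse(!paired, "unpaired",
                  fifelse(bitwAnd(flag, 64L) != 0L, "first", "second"))
  data.table(
    read_id = as.character(lines$V1),
    mate    = mate,
    ref_id  = as.character(lines$V3),
    start   = as.integer(lines$V4) - 1L,
    end     = as.integer(lines$V4) - 1L + span,
    strand  = fifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  )
}

#' Write a result table as TSV with the pipeline's reporting precision
#'
#' M and A statistics and fold changes are written with 2 decimals, percent
#' identities as integers; everything else verbatim.  Row order is made
#' deterministic (by `gene_id` when present, else by descending
#' `reported_identity`).
#'
#' @param records A data.frame/data.table of homogeneous records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(records, path) {
  dt <- as.data.table(records)
  if (nrow(dt) > 0L) {
    if ("gene_id" %in% names(dt)) {
      setorderv(dt, "gene_id")
    } else if ("reported_identity" %in% names(dt)) {
      setorderv(dt, "reported_identity", order = -1L)
    }
    for (col in intersect(c("M", "A", "fold_change", "mean_rpkm_ref",
                            "mean_rpkm_trt", "delta_cp", "sd_delta",
                            "rel_amount"), names(dt))) {
      set(dt, j = col, value = formatC(dt[[col]], format = "f", digits = 2))
    }
    for (col in intersect(c("reported_identity", "pct_identity"), names(dt))) {
      set(dt, j = col, value = format(round_half_up(dt[[col]]),
                                      scientific = FALSE, trim = TRUE))
    }
  }
  ok <- tryCatch({
    fwrite(dt, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

# round-half-up (base round() is half-to-even); used for reported identities
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
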