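# Shared fixtures, all built in code.

# Independent brute-force identity oracle: enumerate every offset of the
# shorter sequence within the longer, counting matches character by
# character via integer codes.  Kept deliberately separate from the
# package's implementation.
oracle_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  acgt <- vapply(c("A", "C", "G", "T"), utf8ToInt, integer(1L))
  best <- -1L
  for (off in 0:(length(bv) - length(av))) {
    m <- 0L
    for (i in seq_along(av)) {
      if (av[i] %in% acgt && av[i] == bv[off + i]) m <- m + 1L
    }
    if (m > best) best <- m
  }
  floor(100 * best / length(av) + 0.5)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Minimal SAM writer for hand-built records
write_test_sam <- function(records, path, ref = "chr1", ref_len = 100000L) {
  lines <- c("@HD\tVN:1.6",
             paste0("@SQ\tSN:", ref, "\tLN:", ref_len),
             vapply(records, function(r) paste(r, collapse = "\t"),
                    character(1L)))
  writeLines(lines, path)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar) {
  c(qname, flag, rname, pos, "255", cigar, "*", "0", "0", "*", "*")
}

# Small annotation table in internal coordinates
test_annotation <- function() {
  data.table::data.table(
    gene_id = c("SCO0001", "SCO0002", "SCO0003"),
    ref_id = "chr1",
    start = c(100L, 1000L, 5000L),
    end = c(700L, 2200L, 5900L),
    strand = c("+", "-", "+"),
    length_bp = c(600L, 1200L, 900L))
}

# Read table for assembly tests
make_reads <- function(...) {
  data.table::rbindlist(lapply(list(...), function(r) {
    data.table::data.table(read_id = r[[1]], mate = r[[2]], ref_id = r[[3]],
                           start = as.integer(r[[4]]),
                           end = as.integer(r[[5]]), strand = r[[6]])
  }))
}
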