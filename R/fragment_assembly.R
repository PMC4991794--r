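# Pair combination: forward and reverse mates, if both mapped to the same
# reference within 1 kb, are combined into one fragment spanning the
# sequenced insert; wider or cross-reference pairs are discarded; lone mates
# are retained as single-mapping fragments.

#' Assemble mapped mate pairs into counting fragments
#'
#' Each `read_id` group is resolved into at most one fragment:
#' * both mates mapped, same reference, outer span (max end - min start)
#'   `<= max_distance` -> one fragment over the span, `origin = "paired"`,
#'   strand taken from the first mate;
#' * both mates mapped but span `> max_distance` or references differ ->
#'   the pair is discarded (counted);
#' * exactly one mate mapped -> a fragment equal to that mate's interval,
#'   `origin = "single"`; a lone *second* mate has its strand flipped so all
#'   fragment strands are in forward-library orientation.
#'
#' Read conservation holds on every input:
#' `2 * combined + 2 * discarded + singles = accepted reads` (reads dropped
#' by the multimap policy are not accepted).
#'
#' @param reads `data.table` of mapped reads as from [read_mapped_reads()].
#' @param max_distance Maximum fragment span in bp (default 1000).
#' @param multimap Policy for `read_id`s with duplicate `(read_id, mate)`
#'   mappings: `"drop"` (default, drop the whole read_id) or `"first"`
#'   (keep the first mapping per mate).
#' @return A list with `fragments` (`data.table`: `ref_id`, `start`, `end`,
#'   `strand`, `origin`) and `stats` (named list: `combined`, `discarded`,
#'   `singles`, `multimapped_reads_dropped`, `total_accepted_reads`).
#' @export
assemble_fragments <- function(reads, max_distance = 1000,
                               multimap = c("drop", "first")) {
  multimap <- match.arg(multimap)
  rd <- as.data.table(reads)
  stopifnot(all(c("read_id", "mate", "ref_id", "start", "end", "strand")
                %in% names(rd)))

  dropped_mm <- 0L
  dup <- duplicated(rd, by = c("read_id", "mate"))
  if (any(dup)) {
    if (multimap == "drop") {
      bad_ids <- unique(rd$read_id[dup])
      dropped_mm <- sum(rd$read_id %in% bad_ids)
      message("multimap policy 'drop': ", dropped_mm, " read(s) from ",
              length(bad_ids), " read_id(s) dropped")
      rd <- rd[!read_id %in% bad_ids]
    } else {
      rd <- rd[!dup]
      dropped_mm <- sum(dup)
    }
  }
  total_accepted <- nrow(rd)

  un <- rd[mate == "unpaired"]
  f1 <- rd[mate == "first"]
  f2 <- rd[mate == "second"]
  pr <- merge(f1, f2, by = "read_id", all = TRUE,
              suffixes = c("_1", "_2"))

  both   <- !is.na(pr$ref_id_1) & !is.na(pr$ref_id_2)
  same   <- both & pr$ref_id_1 == pr$ref_id_2
  span   <- pmax(pr$end_1, pr$end_2) - pmin(pr$start_1, pr$start_2)
  proper <- same & span <= max_distance

  paired_fr <- pr[proper, .(ref_id = ref_id_1,
                            start = pmin(start_1, start_2),
                            end = pmax(end_1, end_2),
                            strand = strand_1,
                            origin = "paired")]
  only1 <- pr[!both & !is.na(ref_id_1),
              .(ref_id = ref_id_1, start = start_1, end = end_1,
                strand = strand_1, origin = "single")]
  # lone second mates: reverse-complement orientation of the library
  only2 <- pr[!both & !is.na(ref_id_2),
              .(ref_id = ref_id_2, start = start_2, end = end_2,
                strand = fifelse(strand_2 == "+", "-", "+"),
                origin = "single")]
  un_fr <- un[, .(ref_id, start, end, strand, origin = "single")]

  fragments <- rbindlist(list(paired_fr, only1, only2, un_fr))
  setorder(fragments, ref_id, start, end)

  stats <- list(
    combined  = sum(proper),
    discarded = sum(both & !proper),
    singles   = nrow(only1) + nrow(only2) + nrow(un_fr),
    multimapped_reads_dropped = dropped_mm,
    total_accepted_reads = total_accepted
  )
  list(fragments = fragments[], stats = stats)
}
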