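test_that("ungapped identity reproduces the reference operator comparisons", {
  cases <- list(
    # candidate, reported identity, best offset
    list("CCGGGCCGCT", 90L, 0L),        # 9/10 at offset 0
    list("GGCCGCGACCC", 91L, 3L),       # 10/11 at offset 3
    list("CCGTGCCGCGTTCCG", 87L, 0L),   # 13/15
    list("CCGGCGCGGTCCCG", 71L, 1L),    # 10/14
    list("CGGTGCGCCGTCCCG", 73L, 1L),   # 11/15
    list("CCGCGGCACGGCCCG", 73L, 0L),   # 11/15
    list(REFERENCE_SITE, 100L, 0L))
  for (cs in cases) {
    h <- ungapped_identity(cs[[1]])
    expect_equal(h$reported_identity, cs[[2]], info = cs[[1]])
  }
  expect_equal(ungapped_identity("CCGGGCCGCT")$best_offset, 0L)
  expect_error(ungapped_identity(""), "empty")
})

test_that("identity is symmetric and matches the brute-force oracle on random pairs", {
  set.seed(41)
  for (i in 1:200) {
    a <- random_seq(sample(8:20, 1), gc = 0.72)
    b <- random_seq(sample(8:20, 1), gc = 0.72)
    expect_equal(ungapped_identity(a, b)$reported_identity, oracle_identity(a, b))
    expect_equal(ungapped_identity(a, b)$pct_identity,
                 ungapped_identity(b, a)$pct_identity)
  }
})

test_that("k mutations of an exact reference copy give identity 100(L-k)/L", {
  set.seed(42)
  ref <- REFERENCE_SITE
  L <- nchar(ref)
  bases <- c("A", "C", "G", "T")
  for (k in 1:5) {
    s <- strsplit(ref, "")[[1]]
    pos <- sample(L, k)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    mut <- paste(s, collapse = "")
    expect_equal(ungapped_identity(mut, ref)$pct_identity, 100 * (L - k) / L)
  }
  # non-ACGT characters never match but count in the length
  expect_equal(ungapped_identity("NNNNNNNNNNNNNNNN", ref)$pct_identity, 0)
})

test_that("scanning finds a planted exact site with the documented distance", {
  set.seed(43)
  region <- random_seq(200, gc = 0.72)
  substr(region, 101, 116) <- REFERENCE_SITE   # 0-based positions 100-115
  hits <- scan_upstream(region, min_identity = 100)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pct_identity, 100)
  expect_equal(hits$distance_to_start, 84L)    # 200 - 116

  # nothing planted, perfect identity required -> empty
  empty <- scan_upstream(random_seq(200, gc = 0.72), min_identity = 100)
  expect_equal(nrow(empty), 0L)
  expect_error(scan_upstream(region, len_range = c(20, 10)), "inverted")
})

test_that("overlapping hits resolve to non-overlapping winners by identity then length", {
  region <- paste0(strrep("A", 50), REFERENCE_SITE, strrep("A", 50))
  hits <- scan_upstream(region, min_identity = 90, len_range = c(10, 16))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$candidate, REFERENCE_SITE)   # longest 100% window wins
  if (nrow(hits) > 1) {
    s <- hits$upstream_position; e <- s + nchar(hits$candidate)
    expect_true(all(e[-length(e)] <= s[-1]))
  }
})

test_that("reverse-complement scanning reports minus-strand sites", {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(REFERENCE_SITE)))
  region <- paste0(strrep("A", 60), rc, strrep("A", 40))
  fwd <- scan_upstream(region, min_identity = 100, len_range = c(16, 16))
  expect_equal(nrow(fwd), 0L)
  both <- scan_upstream(region, min_identity = 100, len_range = c(16, 16),
                        revcomp = TRUE)
  expect_equal(both$strand, "-")
  expect_equal(both$upstream_position, 60L)
})

test_that("empirical null of high-GC regions: no perfect hits, some at 85%", {
  # GC-rich random sequence resembles a GC-rich operator often enough that
  # ~85% identity occurs by chance in a sizeable minority of 200-bp regions
  # (measured ~20% of regions under this seed); perfect matches do not occur
  set.seed(99)
  regions <- replicate(20, random_seq(200, gc = 0.72))
  hits85 <- vapply(regions,
                   function(r) nrow(scan_upstream(r, min_identity = 85)) > 0,
                   logical(1))
  hits100 <- vapply(regions,
                    function(r) nrow(scan_upstream(r, min_identity = 100)) > 0,
                    logical(1))
  expect_false(any(hits100))
  expect_lt(mean(hits85), 0.5)   # common but far from ubiquitous
})

test_that("information content spans 0 to 2 bits and ignores site order", {
  # columns: {C,C,C,C} = 2 bits, {A,C,G,T} = 0, {C,G,T,A} = 0, {C,C,C,C} = 2
  ic <- information_content(c("CACC", "CCGC", "CGTC", "CTAC"))
  expect_equal(ic$bits, c(2, 0, 0, 2), tolerance = 1e-12)
  # two equiprobable bases = 1 bit
  ic2 <- information_content(c("CC", "CC", "GG", "GG"))
  expect_equal(ic2$bits, c(1, 1))
  perm <- information_content(c("GG", "CC", "GG", "CC"))
  expect_equal(perm, ic2)
  expect_error(information_content(c("AC", "ACG")), "equal length")
  expect_error(information_content("AC"), ">= 2 sites")
})

test_that("gaps are excluded from column frequencies; correction lowers bits", {
  ic <- information_content(c("C-", "C-", "CA", "CA"))
  expect_equal(ic$bits[1], 2)
  expect_equal(ic$bits[2], 2)    # only the two non-gap As count
  corr <- information_content(c("CC", "CC", "CC", "CC"), correction = TRUE)
  expect_equal(corr$bits, rep(2 - 3 / (2 * log(2) * 4), 2))
})
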