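test_that("M and A statistics from replicate RPKMs", {
  s <- ma_statistics(c(4, 4), c(32, 32))
  expect_equal(s$M, 3.0)
  expect_equal(s$A, 3.5)
  s0 <- ma_statistics(c(8, 8), c(8, 8))
  expect_equal(s0$M, 0)
  expect_equal(s0$A, 3)
  # replicates averaged before the log: means 4 and 32
  s2 <- ma_statistics(c(3, 5), c(24, 40))
  expect_equal(s2$M, 3.0)
  expect_error(ma_statistics(c(1, -1), c(2, 2)), "non-positive")
})

test_that("fold change is 2^M and inverts under sign flip", {
  expect_equal(fold_change(0), 1)
  expect_equal(round(fold_change(3.19), 2), 9.13)
  expect_equal(round(fold_change(-2.03), 2), 0.24)
  for (M in c(-3, -0.7, 0.1, 2.5)) {
    expect_equal(fold_change(M) * fold_change(-M), 1)
  }
})

test_that("cutoff calibration: sample sd, 2.58 coefficient, floor at 1.5", {
  cal <- calibrate_cutoff(c(-0.5, 0, 0.5))
  expect_equal(cal$stdev_m, 0.5)
  expect_equal(cal$m_min, 1.29)
  expect_equal(cal$m_effective, 1.5)    # floor wins
  deg <- calibrate_cutoff(rep(0.3, 10))
  expect_equal(deg$stdev_m, 0)
  expect_equal(deg$m_effective, 1.5)
  expect_error(calibrate_cutoff(1.0), ">= 2 M-values")
})

test_that("classification follows the filter and the effective cutoff", {
  cfg <- de_config()
  cal <- list(m_effective = 1.5)
  # passes filters, M = 1.58 -> up
  expect_equal(classify(1.58, TRUE, cal, cfg), "up")
  # filtered regardless of M
  expect_equal(classify(5, FALSE, cal, cfg), "filtered")
  # strict threshold: 1.49 < 1.5 -> non
  expect_equal(classify(1.49, TRUE, cal, cfg), "non")
  expect_equal(classify(-1.5, TRUE, cal, cfg), "down")
})

test_that("a full contrast partitions genes and swapping conditions negates M", {
  set.seed(31)
  n <- 300
  mat <- matrix(2^rnorm(n * 4, mean = 6, sd = 1.5), nrow = n,
                dimnames = list(sprintf("G%03d", 1:n),
                                c("ref1", "ref2", "trt1", "trt2")))
  mat[1:10, c("trt1", "trt2")] <- mat[1:10, c("ref1", "ref2")] * 16
  res <- de_contrast(mat, c("ref1", "ref2"), c("trt1", "trt2"))
  expect_equal(sort(unique(res$results$category)) %in%
                 c("up", "down", "non", "filtered"), rep(TRUE, length(unique(res$results$category))))
  expect_equal(nrow(res$results), n)
  expect_equal(res$results$fold_change, 2^res$results$M)

  swapped <- de_contrast(mat, c("trt1", "trt2"), c("ref1", "ref2"))
  expect_equal(swapped$results$M, -res$results$M)
  expect_equal(swapped$results$A, res$results$A)
})

test_that("the RPKM filter needs only one condition mean at threshold", {
  mat <- matrix(c(25, 25, 28, 28,    # both below 30 -> filtered
                  40, 40, 120, 120,  # one above -> kept
                  400, 400, 410, 410,
                  300, 300, 310, 310),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("low", "asym", "hi1", "hi2"),
                                c("r1", "r2", "t1", "t2")))
  res <- de_contrast(mat, c("r1", "r2"), c("t1", "t2"))
  expect_equal(res$results[gene_id == "low", category], "filtered")
  expect_false(res$results[gene_id == "asym", category] == "filtered")
})

test_that("MA-plot table carries the conventional colour tags", {
  res <- data.table::data.table(
    gene_id = c("a", "b", "c", "d"),
    A = c(5, 6, 7, 8), M = c(2, -2, 0.2, 4),
    category = c("up", "down", "non", "filtered"))
  tab <- ma_plot_table(res)
  expect_equal(nrow(tab), 3L)   # filtered genes are not plotted
  expect_equal(tab$color, c("green", "red", "grey"))
  expect_equal(nrow(ma_plot_table(res[0])), 0L)
})

test_that("self-calibrated cutoff leaves ~1% of standard-normal M outside", {
  set.seed(32)
  M <- rnorm(1e4)
  cal <- calibrate_cutoff(M)
  expect_equal(cal$m_min, 2.58, tolerance = 0.03)
  frac_out <- mean(abs(M) > cal$m_min)
  expect_gt(frac_out, 0.005)
  expect_lt(frac_out, 0.02)
})
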