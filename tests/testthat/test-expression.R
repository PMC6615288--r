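write_toy_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:T1\tLN:1000",
    "@SQ\tSN:T2\tLN:800",
    "@SQ\tSN:TX\tLN:500",
    # three primary reads on T1
    "r1\t0\tT1\t10\t60\t50M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC\t*",
    "r2\t0\tT1\t40\t60\t50M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC\t*",
    "r3\t16\tT1\t80\t60\t50M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC\t*",
    # one secondary (flag 256) on T1: must not count
    "r4\t256\tT1\t10\t0\t50M\t*\t0\t0\t*\t*",
    # one supplementary (flag 2048) on T2: must not count
    "r5\t2048\tT2\t10\t0\t50M\t*\t0\t0\t*\t*",
    # primary on T2, unmapped read (flag 4), and one on a foreign reference
    "r6\t0\tT2\t5\t60\t50M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC\t*",
    "r7\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",
    "r8\t0\tTX\t5\t60\t50M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC\t*")
  writeLines(lines, path)
  path
}

test_that("SAM counting keeps primary alignments only and skips foreign references", {
  sam <- write_toy_sam(tempfile(fileext = ".sam"))
  expect_warning(counts <- count_reads(sam, c("T1", "T2", "T3")),
                 "not in transcript set")
  expect_identical(counts, c(T1 = 3L, T2 = 1L, T3 = 0L))
})

test_that("count tables are ingested and a zero library refuses RPKM", {
  df <- data.frame(transcript_id = c("a", "b"), count = c(5L, 0L))
  counts <- count_reads(df, c("a", "b", "c"))
  expect_identical(counts, c(a = 5L, b = 0L, c = 0L))
  expect_error(expression_records(c(a = 0L, b = 0L), c(a = 500L, b = 300L)),
               "library size is 0")
})

test_that("rpkm follows its closed form and scale properties", {
  expect_equal(rpkm(10, 1e6, 500), 20)
  expect_equal(rpkm(0, 1e6, 500), 0)
  expect_equal(rpkm(20, 2e6, 500), rpkm(10, 1e6, 500))       # joint scaling
  expect_equal(rpkm(30, 1e6, 500), 3 * rpkm(10, 1e6, 500))   # linear in count
  expect_error(rpkm(1, 0, 500), "library_size")
  expect_error(rpkm(1, 10, 0), "length_nt")
})

test_that("expression records carry RPKM and the 2-read support flag", {
  rec <- expression_records(c(a = 10L, b = 1L, c = 0L),
                            c(a = 500L, b = 1000L, c = 200L))
  expect_equal(rec$rpkm[1], 10 * 1e9 / (11 * 500))
  expect_identical(rec$supported, c(TRUE, FALSE, FALSE))
  expect_true(all(rec$rpkm == 0 | rec$count > 0))
})

test_that("abundance t-test handles identical and degenerate groups", {
  same <- group_abundance_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- group_abundance_test(c(1, 1, 1, 1), c(3, 3, 3, 3))
  expect_true(const$exact_separation)
  expect_equal(const$p_value, 0)
  expect_error(group_abundance_test(1, c(1, 2)), ">= 2")
  # detects a genuine shift
  shift <- group_abundance_test(c(10, 12, 9, 11), c(1, 2, 1.5, 1))
  expect_lt(shift$p_value, 0.01)
})

test_that("differential expression matches the exact binomial enumeration", {
  ids <- c("t1", "t2")
  de <- differential_expression(setNames(c(16L, 5L), ids), setNames(c(1L, 5L), ids),
                                lib_a = 1e6, lib_b = 1e6)
  # log2((16.5/1e6)/(1.5/1e6)) and two-sided min-likelihood binomial p
  expect_equal(de$log2_fold_change[1], log2(16.5 / 1.5), tolerance = 1e-12)
  expect_equal(de$p_value[1], 2 * (1 + 17) / 2^17, tolerance = 1e-12)
  expect_true(de$significant[1])
  expect_equal(de$log2_fold_change[2], 0)
  expect_false(de$significant[2])
  # zero-total transcripts are excluded
  de0 <- differential_expression(c(x = 0L, y = 3L), c(x = 0L, y = 9L),
                                 lib_a = 100L, lib_b = 100L)
  expect_identical(de0$transcript_id, "y")
})

test_that("differential expression is antisymmetric under condition swap", {
  set.seed(41)
  a <- setNames(rpois(50, 40), paste0("t", 1:50))
  b <- setNames(rpois(50, 40), paste0("t", 1:50))
  d1 <- differential_expression(a, b, lib_a = 5000, lib_b = 6000)
  d2 <- differential_expression(b, a, lib_a = 6000, lib_b = 5000)
  expect_equal(d1$log2_fold_change, -d2$log2_fold_change, tolerance = 1e-12)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
})

test_that("binomial p-values are near-uniform under a sampling null", {
  set.seed(43)
  n <- 2000
  mu <- rlnorm(n, log(400), 0.5)
  a <- setNames(rpois(n, mu), paste0("g", 1:n))
  b <- setNames(rpois(n, mu), paste0("g", 1:n))
  de <- differential_expression(a, b, lib_a = 1e6, lib_b = 1e6)
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
})
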