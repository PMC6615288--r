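test_that("GTF exon lines become transcripts with correct coordinates and lengths", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  tx <- read_transcript_gtf(gtf)
  expect_length(tx, 1)
  expect_identical(unname(spliced_length(tx)), 200L)
  expect_identical(start(tx[["t1"]]), c(1L, 201L))
  expect_identical(end(tx[["t1"]]), c(100L, 300L))
})

test_that("empty GTF yields an empty transcript set without error", {
  f <- tempfile(fileext = ".gtf")
  file.create(f)
  expect_length(read_transcript_gtf(f), 0)
})

test_that("GTF strand '.' maps to unknown, and missing gene_id is tolerated", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t10\t60\t.\t.\t.\ttranscript_id "t1";',
    'chr1\tsrc\texon\t120\t180\t.\t.\t.\ttranscript_id "t1";'), gtf)
  tx <- read_transcript_gtf(gtf)
  expect_identical(as.character(unique(GenomicRanges::strand(tx[["t1"]]))), "*")
  expect_true(is.na(S4Vectors::mcols(tx)$gene_id))
})

test_that("write-read round trip is a fixed point on canonical records", {
  tx <- make_tx(list(a = cbind(c(1, 301), c(100, 400)),
                     b = cbind(50, 420)),
                strand = c("-", "*"))
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_transcript_gtf(tx, f1)
  tx2 <- read_transcript_gtf(f1)
  write_transcript_gtf(tx2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(names(tx2), names(tx))
  expect_identical(unname(spliced_length(tx2)), unname(spliced_length(tx)))
})

test_that("overlap_bp matches definition cases and a per-base counting oracle", {
  g <- function(chr, s, e) GenomicRanges::GRanges(chr, IRanges::IRanges(s, e))
  expect_identical(overlap_bp(g("chr1", 1, 100), g("chr1", 51, 150)), 50L)
  # half-open adjacency in 0-based terms = abutting closed intervals share 0 bp
  expect_identical(overlap_bp(g("chr1", 1, 100), g("chr1", 101, 200)), 0L)
  expect_identical(overlap_bp(g("chr1", 1, 100), g("chr2", 1, 100)), 0L)

  set.seed(42)
  for (i in 1:1000) {
    ca <- sample(c("chr1", "chr2"), 1); cb <- sample(c("chr1", "chr2"), 1)
    sa <- sample(500, 1); ea <- sa + sample(0:80, 1)
    sb <- sample(500, 1); eb <- sb + sample(0:80, 1)
    expect_identical(overlap_bp(g(ca, sa, ea), g(cb, sb, eb)),
                     oracle_overlap_bp(ca, sa, ea, cb, sb, eb))
  }
})

test_that("interval queries against the annotation index equal a brute-force scan", {
  set.seed(7)
  exons <- lapply(1:40, function(i) {
    s <- sample(20000, 1)
    cbind(s, s + sample(100:800, 1))
  })
  names(exons) <- sprintf("t%02d", 1:40)
  tx <- make_tx(exons, chrom = sample(c("chr1", "chr2"), 40, replace = TRUE))
  ann <- annotation_set(tx)
  spans <- ann$genes
  for (i in 1:1000) {
    chr <- sample(c("chr1", "chr2"), 1)
    s <- sample(21000, 1); q <- GenomicRanges::GRanges(chr, IRanges::IRanges(s, s + sample(300, 1)))
    got <- sort(query_annotation(ann, q)[[1]])
    want <- sort(names(spans)[vapply(seq_along(spans), function(j) {
      oracle_overlap_bp(chr, start(q), end(q),
                        as.character(GenomicRanges::seqnames(spans))[j],
                        start(spans)[j], end(spans)[j]) > 0
    }, logical(1))])
    expect_identical(got, want)
  }
})

test_that("spliced_sequence honors strand and flags unknown-strand models", {
  g <- Biostrings::DNAStringSet(c(chrT = "ACGTACGT"))
  tx <- make_tx(list(t = cbind(c(1, 5), c(2, 6))), chrom = "chrT", strand = "+")
  expect_identical(as.character(spliced_sequence(tx, g)[[1]]), "ACAC")
  tx_m <- make_tx(list(t = cbind(c(1, 5), c(2, 6))), chrom = "chrT", strand = "-")
  expect_identical(as.character(spliced_sequence(tx_m, g)[[1]]), "GTGT")
  tx_u <- make_tx(list(t = cbind(c(1, 5), c(2, 6))), chrom = "chrT", strand = "*")
  s <- spliced_sequence(tx_u, g)
  expect_identical(as.character(s[[1]]), "ACAC")
  expect_true(S4Vectors::mcols(s)$both_strands)
  # out-of-bounds exon errors
  tx_bad <- make_tx(list(t = cbind(5, 20)), chrom = "chrT")
  expect_error(spliced_sequence(tx_bad, g), "beyond")
})

test_that("spliced sequence length always equals the sum of exon widths", {
  set.seed(11)
  g <- Biostrings::DNAStringSet(c(chr1 = random_seq(5000)))
  exons <- lapply(1:20, function(i) {
    k <- sample(1:4, 1)
    s <- sort(sample(4500, k))
    s <- s[c(TRUE, diff(s) > 120)]
    cbind(s, s + sample(20:100, length(s), replace = TRUE))
  })
  names(exons) <- paste0("t", seq_along(exons))
  tx <- make_tx(exons, strand = sample(c("+", "-", "*"), 20, replace = TRUE))
  seqs <- spliced_sequence(tx, g)
  expect_identical(unname(Biostrings::width(seqs)), unname(unclass(spliced_length(tx))))
})

test_that("transcript validation rejects malformed exon chains", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50), c(100, 160)),
                               strand = "+", transcript_id = "t1")
  expect_error(transcript_models(gr), "disjoint")
  gr2 <- GenomicRanges::GRanges(c("chr1", "chr2"), IRanges::IRanges(c(1, 500), c(100, 600)),
                                strand = "+", transcript_id = "t1")
  expect_error(transcript_models(gr2), "one chromosome")
})
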