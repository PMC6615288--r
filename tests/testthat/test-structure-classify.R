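# a small reference: two multi-exon coding genes, one lncRNA, one snoRNA-like
toy_reference <- function() {
  ex <- list(
    cod1 = cbind(c(1000, 2000, 3000), c(1500, 2500, 3600)),
    cod2 = cbind(c(10000, 12000), c(10800, 12900)),
    lnc1 = cbind(c(20000, 21000), c(20400, 21500)),
    srna1 = cbind(30000, 30120))
  tx <- make_tx(ex, strand = c("+", "-", "+", "+"))
  annotation_set(tx, c(cod1 = "protein_coding", cod2 = "protein_coding",
                       lnc1 = "lncRNA", srna1 = "other_ncRNA"))
}

test_that("perfect structural matches and intergenic transcripts are recognized", {
  ref <- toy_reference()
  tx <- make_tx(list(
    same = cbind(c(1010, 2000, 3000), c(1500, 2500, 3590)),  # identical chain, close ends
    far = cbind(c(50000, 51000), c(50400, 51500))),          # overlaps nothing
    strand = "*")
  m <- classify_transcripts(tx, ref)
  expect_identical(m$match_score, c(5L, 0L))
  expect_identical(m$class_code, c("=", "u"))
  expect_identical(m$best_ref_transcript[1], "cod1")
  expect_true(m$shares_intron[1])
  expect_false(m$shares_intron[2])
})

test_that("class codes and scores match the brute-force oracle on random transcripts", {
  set.seed(61)
  ref <- toy_reference()
  refs_plain <- as_plain_tx(ref$transcripts)
  genes_plain <- lapply(seq_along(ref$genes), function(i) {
    list(chrom = as.character(GenomicRanges::seqnames(ref$genes))[i],
         start = start(ref$genes)[i], end = end(ref$genes)[i])
  })
  exons <- list(); strands <- character(0)
  for (i in 1:200) {
    k <- sample(1:3, 1)
    s <- sample(35000, 1)
    widths <- sample(50:500, k, replace = TRUE)
    introns <- if (k > 1) sample(50:800, k - 1, replace = TRUE) else integer(0)
    starts <- s + cumsum(c(0, widths[-k] + introns))
    exons[[sprintf("r%03d", i)]] <- cbind(starts, starts + widths - 1)
    strands[i] <- sample(c("+", "-", "*"), 1)
  }
  # also plant exact and near matches so high scores are exercised
  exons$plant1 <- cbind(c(1000, 2000, 3000), c(1500, 2500, 3600))
  exons$plant2 <- cbind(c(2000, 3000), c(2500, 3600))   # contiguous subchain
  exons$plant3 <- cbind(c(1600, 2000), c(1900, 2500))   # shares junction 1501..1999? no: intron 1901-1999
  strands <- c(strands, "*", "*", "*")
  tx <- make_tx(exons, strand = strands)
  m <- classify_transcripts(tx, ref)
  plain <- as_plain_tx(tx)
  for (i in seq_along(plain)) {
    o <- oracle_classify(plain[[i]], refs_plain, genes_plain)
    expect_identical(m$match_score[i], o$score)
    expect_identical(m$class_code[i], o$class)
  }
})

test_that("lincRNA selection keeps multi-exon intergenic transcripts only", {
  ref <- toy_reference()
  tx <- make_tx(list(
    multi_far = cbind(c(50000, 51000), c(50400, 51500)),   # 50 kb from genes
    mono_far = cbind(60000, 61000)), strand = "*")
  m <- classify_transcripts(tx, ref)
  calls <- select_lincRNAs(tx, m, ref)
  expect_true(calls$is_lincRNA[calls$transcript_id == "multi_far"])
  expect_false(calls$is_lincRNA[calls$transcript_id == "mono_far"])
  expect_identical(calls$drop_reason[calls$transcript_id == "mono_far"], "single_exon")
})

test_that("transcripts sharing a coding intron or matching structures are dropped", {
  ref <- toy_reference()
  tx <- make_tx(list(
    # same intron chain as cod1, jittered ends -> perfect match, dropped
    perfect = cbind(c(1050, 2000, 3000), c(1500, 2500, 3550)),
    # identical chain to known lncRNA -> kept as lincRNA (known structure)
    known_lnc = cbind(c(20000, 21000), c(20400, 21500)),
    # shares cod2's intron but exons extend outside the gene span
    intron_sharer = cbind(c(9500, 12000), c(10800, 13500))),
    strand = "*")
  m <- classify_transcripts(tx, subset_biotype(ref, c("protein_coding", "other_ncRNA")))
  calls <- select_lincRNAs(tx, m, subset_biotype(ref, c("protein_coding", "other_ncRNA")),
                           lnc_ref = subset_biotype(ref, "lncRNA"))
  expect_identical(calls$drop_reason[1], "perfect_structure_match")
  expect_true(calls$is_lincRNA[2])
  expect_identical(calls$novelty[2], "known_structure")
  expect_identical(calls$drop_reason[3], "shares_coding_intron")
})

test_that("selected lincRNAs never overlap a protein-coding gene span", {
  res <- default_pipeline()
  sim <- default_sim()
  coding_spans <- sim$reference$genes[sim$reference$genes$biotype == "protein_coding"]
  expect_length(res$lincRNAs, sum(res$calls$is_lincRNA))
  if (length(res$lincRNAs)) {
    ov <- GenomicRanges::findOverlaps(res$lincRNAs, coding_spans, ignore.strand = TRUE)
    expect_length(ov, 0)
    expect_true(all(n_exons(res$lincRNAs) >= 2))
  }
})

test_that("locus clustering equals connected components of the overlap graph", {
  tx <- make_tx(list(a = cbind(c(100, 600), c(300, 900)),
                     b = cbind(c(250, 1500), c(700, 1800)),   # overlaps a
                     c = cbind(3000, 3500)))                  # 1+ kb away
  loci <- cluster_loci(tx)
  expect_identical(loci[1], loci[2])
  expect_false(loci[1] == loci[3])

  set.seed(71)
  exons <- lapply(1:60, function(i) {
    s <- sample(30000, 1)
    k <- sample(1:3, 1)
    starts <- s + cumsum(c(0, rep(600, k - 1)))
    cbind(starts, starts + 280)
  })
  names(exons) <- paste0("t", 1:60)
  tx2 <- make_tx(exons, chrom = sample(c("chr1", "chr2"), 60, replace = TRUE))
  got <- cluster_loci(tx2)
  plain <- as_plain_tx(tx2)
  want <- oracle_components(60, function(v, w) plain_exon_overlap(plain[[v]], plain[[w]]))
  # same partition (labels may differ)
  expect_identical(table(got, want) > 0, table(got, want) > 0)
  expect_equal(length(unique(got)), length(unique(want)))
  for (g in unique(want)) {
    expect_length(unique(got[want == g]), 1)
  }
})

test_that("annotation comparison labels shared, shifted and unique transcripts", {
  a <- make_tx(list(shared = cbind(c(100, 600), c(300, 900)),
                    shifted = cbind(c(5100, 5700), c(5400, 6000)),
                    unique = cbind(c(20000, 20600), c(20300, 20900))),
               strand = "+")
  b <- make_tx(list(s1 = cbind(c(100, 600), c(300, 900)),
                    s2 = cbind(c(5100, 5650), c(5350, 6000))),
               strand = "+")
  cmp <- compare_annotations(a, b)
  expect_identical(cmp$status, c("same_structure", "overlap_only", "absent"))
  cmp_same <- compare_annotations(a, a)
  expect_true(all(cmp_same$status == "same_structure"))
})
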