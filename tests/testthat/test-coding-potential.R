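test_that("ORF finder handles the definition cases", {
  orfs <- find_orfs("ATGAAATAG")
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$frame, 0)
  expect_equal(orfs$peptide_length, 2)
  expect_true(orfs$has_stop)
  expect_equal(nrow(find_orfs("CCCCCC")), 0)
  # ORF without a stop runs to the last full codon
  open <- find_orfs("CCATGAAAAA")
  expect_equal(open$start, 3)
  expect_equal(open$end, 8)
  expect_false(open$has_stop)
  # N-containing codons are neither start nor stop
  expect_equal(nrow(find_orfs("ANGAAATAG")), 0)
  withN <- find_orfs("ATGTNAAAATAA")
  expect_equal(withN$peptide_length[1], 3)  # TNA is not a stop; ends at TAA
})

test_that("ORF finder agrees with a positional brute-force oracle on random sequences", {
  set.seed(23)
  canon <- function(df) {
    df <- df[order(df$orf_strand, df$frame, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  for (i in 1:100) {
    n <- sample(60:400, 1)
    letters <- if (i %% 10 == 0) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    s <- random_seq(n, letters)
    got <- canon(find_orfs(s, both_strands = TRUE))
    want <- oracle_find_orfs(s, both_strands = TRUE)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got, canon(want))
    }
  }
})

test_that("TESTCODE score stabilises under duplication and matches an independent implementation", {
  set.seed(31)
  s <- random_seq(300)
  # concatenating frame-preserving copies leaves all ratios asymptotically
  # unchanged; with counts this large the +1 of the position parameter is
  # negligible and the binned score is exactly stable
  expect_equal(fickett_testcode(strrep(s, 40)), fickett_testcode(strrep(s, 80)),
               tolerance = 1e-9)
  expect_lt(abs(fickett_testcode(paste0(s, s)) - fickett_testcode(s)), 0.15)
  expect_equal(fickett_testcode(strrep("ATG", 100)),
               oracle_fickett(strrep("ATG", 100)), tolerance = 1e-12)
  for (i in 1:25) {
    r <- random_seq(sample(200:900, 1))
    expect_equal(fickett_testcode(r), oracle_fickett(r), tolerance = 1e-12)
  }
  rng <- lincforge:::fickett_score_range()
  for (i in 1:2) {
    sc <- fickett_testcode(random_seq(1000))
    expect_gte(sc, rng[1]); expect_lte(sc, rng[2])
  }
  expect_error(fickett_testcode("NNNNNN"), "no A/C/G/T")
})

test_that("hexamer bias follows its definition", {
  all6 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)
  zero <- setNames(rep(0, 4096), all6)
  expect_equal(hexamer_bias(random_seq(120), zero), 0)
  tab <- zero; tab["ATGGCC"] <- 1
  expect_equal(hexamer_bias("ATGGCCGCC", tab), 0.5)  # hits at offsets 1 and 4
  expect_equal(hexamer_bias("ATNGCCGCC", tab), 0)    # N-containing hexamer skipped
  expect_equal(hexamer_bias("ACGT", tab), 0)         # too short
})

test_that("hexamer table training smooths degenerate input and zeroes identical classes", {
  set.seed(37)
  same <- Biostrings::DNAStringSet(replicate(12, random_seq(120)))
  # identical classes counted with the same stride give the zero table
  tab <- train_hexamer_table(same, same, noncoding_step = 3L)
  expect_true(all(tab == 0))
  # the default asymmetric strides (in-frame vs sliding) do not
  tab_default <- train_hexamer_table(same, same)
  expect_false(all(tab_default == 0))
  homo <- Biostrings::DNAStringSet(rep("AAAAAAAAAAAA", 12))
  tab2 <- train_hexamer_table(homo, same)
  expect_true(all(is.finite(tab2)))
  expect_error(train_hexamer_table(same[1:5], same), "at least 10")
})

test_that("logistic coding probability obeys closed-form and monotonicity contracts", {
  feats <- data.frame(orf_length_nt = c(0, 300, 1200), orf_coverage = c(0, .4, .9),
                      fickett_score = c(.5, 1, 1.2), hexamer_score = c(-1, 0, 2))
  expect_equal(coding_probability(feats, c(0, 0, 0, 0, 0)), rep(0.5, 3))
  p_lo <- coding_probability(feats, c(-1, .001, 1, 1, 1))
  p_hi <- coding_probability(feats, c(5, .001, 1, 1, 1))
  expect_true(all(p_hi > p_lo))  # monotone increasing in the intercept
  expect_true(all(coding_probability(feats, c(1e3, 0, 0, 0, 0)) > 1 - 1e-9))
  # monotone non-decreasing in a feature with positive weight
  f2 <- feats; f2$hexamer_score <- f2$hexamer_score + 1
  w <- c(0, .001, 1, 1, 1)
  expect_true(all(coding_probability(f2, w) >= coding_probability(feats, w)))
})

test_that("generator-trained model separates planted coding from noncoding sequences", {
  sim <- default_sim()
  tab <- train_hexamer_table(sim$cds, sim$training_noncoding)
  hx_cod <- vapply(as.character(sim$cds)[1:30], hexamer_bias, numeric(1), table = tab)
  hx_non <- vapply(as.character(sim$training_noncoding)[1:30], function(s) {
    orf <- lincforge:::longest_orf(s)
    if (orf$length_nt >= 6) hexamer_bias(orf$seq, tab) else 0
  }, numeric(1))
  expect_gt(mean(hx_cod), mean(hx_non))

  model <- train_coding_model(sim$mrnas, sim$training_noncoding, tab)
  p_cod <- coding_probability(coding_features(sim$mrnas, tab), model)
  p_non <- coding_probability(coding_features(sim$training_noncoding, tab), model)
  acc <- (sum(p_cod > 0.44) + sum(p_non <= 0.44)) / (length(p_cod) + length(p_non))
  expect_gte(acc, 0.9)
})

test_that("coding filters implement the worded strict inequalities in order", {
  assessment <- data.frame(
    transcript_id = c("at_cut", "above_cut", "clean"),
    coding_probability = c(0.44, 0.45, 0.10))
  res <- apply_coding_filters(assessment)
  expect_identical(res$keep, c(TRUE, FALSE, TRUE))
  expect_identical(res$reason, c(NA, "coding_probability", NA))

  # protein homology: > 85% identity AND > 50 aa alignment AND > 100 aa ORF
  prot <- data.frame(
    transcript_id = c("clean", "clean", "clean", "clean"),
    peptide_length = c(120, 120, 120, 100),
    identity = c(0.85, 0.851, 0.851, 0.9),
    alignment_length = c(60, 50, 51, 60))
  one <- function(hits) {
    apply_coding_filters(assessment[3, , drop = FALSE], protein_hits = hits)
  }
  expect_true(one(prot[1, ])$keep)    # identity exactly 85% -> keep
  expect_true(one(prot[2, ])$keep)    # alignment exactly 50 aa -> keep
  expect_false(one(prot[3, ])$keep)   # 85.1% over 51 aa -> drop
  expect_identical(one(prot[3, ])$reason, "orf_homology")
  expect_true(one(prot[4, ])$keep)    # ORF exactly 100 aa -> not gated

  # mRNA homology: > 95% identity covering > 50% of the query
  nuc <- data.frame(transcript_id = "clean",
                    identity = c(0.95, 0.951, 0.951),
                    query_coverage = c(0.6, 0.50, 0.501))
  two <- function(i) apply_coding_filters(assessment[3, , drop = FALSE],
                                          nucleotide_hits = nuc[i, ])
  expect_true(two(1)$keep)
  expect_true(two(2)$keep)
  expect_false(two(3)$keep)
  expect_identical(two(3)$reason, "utr_fragment")

  # domain hits drop whatever remains; earlier reasons win
  dom <- data.frame(transcript_id = c("clean", "above_cut"))
  res3 <- apply_coding_filters(assessment, protein_hits = prot[3, ],
                               domain_hits = dom)
  expect_identical(res3$reason, c(NA, "coding_probability", "orf_homology"))
})

test_that("local-alignment homology hits find planted UTR fragments", {
  sim <- default_sim()
  frag_ids <- sim$truth$transcript_id[sim$truth$class == "utr_fragment"][1:4]
  linc_ids <- sim$truth$transcript_id[sim$truth$class == "intergenic_multiexon"][1:4]
  seqs <- spliced_sequence(sim$transcripts[c(frag_ids, linc_ids)], sim$genome)
  hits <- transcript_mrna_hits(seqs, sim$mrnas)
  strong <- hits[hits$identity > 0.95 & hits$query_coverage > 0.5, ]
  expect_true(all(frag_ids %in% strong$transcript_id))
  expect_false(any(linc_ids %in% strong$transcript_id))
})
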