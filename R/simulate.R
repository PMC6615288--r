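# background base composition (slightly AT-rich, mammal-like)
BG_PROB <- c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)

# deterministic biased codon-usage weights: sense codons only, favouring
# G/C in the wobble position and purines at codon start (any strongly
# non-uniform table separates coding from background hexamer statistics)
codon_usage_weights <- function() {
  codons <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3)
  w <- rep(1, length(codons))
  names(w) <- codons
  w[substr(codons, 3, 3) %in% c("C", "G")] <- w[substr(codons, 3, 3) %in% c("C", "G")] + 1.5
  w[substr(codons, 1, 1) %in% c("A", "G")] <- w[substr(codons, 1, 1) %in% c("A", "G")] + 0.5
  w[STOP_CODONS] <- 0
  w
}

#' Parameters of the synthetic transcriptome
#'
#' Defaults describe the study conditions the pipeline is validated under: a
#' 2 Mb genome over 4 chromosomes carrying 60 multi-exon protein-coding
#' genes (codon-biased CDS of 150-400 codons with UTRs), 20 known lncRNA
#' genes and a handful of small structural RNA genes; novel transcript
#' models of six planted classes; strand-unknown
#' novel models with end-jittered redundant copies; and two-condition
#' negative-binomial counts (dispersion 0.2) with a planted fraction of
#' 4-fold changes in condition A.
#'
#' @param seed RNG seed; all draws flow from this single stream.
#' @param genome_length_nt total genome length over `n_chrom` chromosomes.
#' @param n_chrom number of chromosomes.
#' @param n_coding,n_known_lnc,n_other_nc reference gene counts.
#' @param n_novel named counts of planted novel-transcript classes.
#' @param redundancy copies emitted per novel transcript (1 = no copies);
#'   copies are end-jittered within `end_jitter_nt`.
#' @param end_jitter_nt maximum terminal shrink of jittered copies (nt).
#' @param de_fold,de_fraction planted fold change (condition A) and the
#'   fraction of novel transcripts carrying it.
#' @param depth target total reads per condition.
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp*mu^2).
#' @param n_train_noncoding extra background noncoding training sequences.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, genome_length_nt = 2e6, n_chrom = 4L,
                           n_coding = 60L, n_known_lnc = 20L, n_other_nc = 5L,
                           n_novel = c(full_coding = 30L, utr_fragment = 20L,
                                       intronic = 15L, antisense_like = 15L,
                                       intergenic_multiexon = 60L,
                                       intergenic_monoexon = 20L),
                           redundancy = 2L, end_jitter_nt = 80L,
                           de_fold = 4.0, de_fraction = 0.1, depth = 2e5,
                           nb_dispersion = 0.2, n_train_noncoding = 80L) {
  stopifnot(all(n_novel >= 0), de_fraction >= 0, de_fraction <= 1, depth > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

random_dna <- function(n) {
  paste(sample(names(BG_PROB), n, replace = TRUE, prob = BG_PROB), collapse = "")
}

# noncoding sequence with every ORF (both orientations) capped below 100 aa
make_noncoding_seq <- function(n, max_aa = 99L, max_try = 60L) {
  for (i in seq_len(max_try)) {
    s <- random_dna(n)
    orfs <- find_orfs(s, both_strands = TRUE)
    if (!nrow(orfs) || max(orfs$peptide_length) <= max_aa) return(s)
  }
  stop("could not generate an ORF-capped noncoding sequence of length ", n)
}

make_cds <- function(n_codons, weights) {
  body <- sample(names(weights), n_codons - 1L, replace = TRUE, prob = weights)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

# split a spliced length into k exon lengths (each >= min_exon)
exon_lengths <- function(L, k, min_exon = 50L) {
  k <- max(1L, min(k, L %/% min_exon))
  if (k == 1L) return(L)
  extra <- as.vector(stats::rmultinom(1, L - k * min_exon, rep(1, k)))
  min_exon + extra
}

new_placer <- function(chrom_lengths) {
  occ <- lapply(chrom_lengths, function(...) IRanges::IRanges())
  list(
    place = function(len, buffer = 1000L, max_try = 300L) {
      for (i in seq_len(max_try)) {
        chrom <- sample(names(chrom_lengths), 1, prob = chrom_lengths)
        hi <- chrom_lengths[[chrom]] - len - buffer
        if (hi <= buffer) next
        st <- sample.int(hi - buffer, 1) + buffer
        cand <- IRanges::IRanges(st - buffer, st + len - 1L + buffer)
        if (!length(IRanges::findOverlaps(cand, occ[[chrom]]))) {
          occ[[chrom]] <<- c(occ[[chrom]], IRanges::IRanges(st, st + len - 1L))
          return(list(chrom = chrom, start = st))
        }
      }
      stop("no free genomic slot found; increase genome_length_nt")
    })
}

# genomic exon coordinates for a gene of given exon/intron lengths
gene_coords <- function(start, ex_lens, in_lens) {
  starts <- start + c(0L, cumsum(ex_lens[-length(ex_lens)] + in_lens))
  IRanges::IRanges(starts, width = ex_lens)
}

# distribute a spliced sequence over genomic exons, honouring strand
exon_pieces <- function(seq, ex_lens, strand) {
  stops <- cumsum(ex_lens)
  starts <- stops - ex_lens + 1L
  pieces <- substring(seq, starts, stops)
  if (strand == "-") {
    pieces <- rev(vapply(pieces, function(p)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
      character(1)))
  }
  pieces
}

# genomic exon subchain covering the 3'-most `m` spliced nt of a transcript
spliced_tail_region <- function(exons, strand, m) {
  w <- GenomicRanges::width(exons)
  if (strand == "-") {
    # 3' end is the genomic left; walk exons left to right
    cum <- cumsum(w)
    k <- which(cum >= m)[1]
    keep <- exons[seq_len(k)]
    surplus <- cum[k] - m
    end(keep)[k] <- end(keep)[k] - surplus
    keep
  } else {
    cum <- rev(cumsum(rev(w)))
    k <- max(which(cum >= m))
    keep <- exons[k:length(exons)]
    surplus <- cum[k] - m
    start(keep)[1] <- start(keep)[1] + surplus
    keep
  }
}

# shrink the outer ends of an exon chain by up to `max_nt` on each side
jitter_ends <- function(exons, max_nt, min_exon = 30L) {
  s1 <- sample.int(max_nt + 1L, 1) - 1L
  s2 <- sample.int(max_nt + 1L, 1) - 1L
  s1 <- min(s1, GenomicRanges::width(exons)[1] - min_exon)
  s2 <- min(s2, GenomicRanges::width(exons)[length(exons)] - min_exon)
  if (s1 > 0) start(exons)[1] <- start(exons)[1] + s1
  if (s2 > 0) end(exons)[length(exons)] <- end(exons)[length(exons)] - s2
  exons
}

#' Generate a fully labelled synthetic transcriptome
#'
#' Builds a random background genome, writes reference genes into it
#' (protein-coding genes with biased-codon CDS and UTRs, multi-exon known
#' lncRNA genes, small structural RNA genes), and emits novel transcript
#' models of six planted classes: `full_coding` (end-jittered coding
#' isoforms), `utr_fragment` (3'-UTR tail fragments), `intronic` (inside
#' coding-gene introns), `antisense_like` (exon-overlapping, opposite
#' strand), `intergenic_multiexon` (the planted true lincRNAs: known-lncRNA
#' copies, novel isoforms at known lncRNA loci, and fresh intergenic loci,
#' all at least 1 kb from every gene span) and `intergenic_monoexon`
#' (single-exon intergenic, excluded by the multi-exon rule). Novel models
#' have unknown strand and are emitted with `redundancy` end-jittered
#' copies. Two-condition counts are drawn per transcript from a negative
#' binomial around planted means (lincRNA means lower than coding means),
#' with a `de_fraction` of transcripts boosted `de_fold`-fold in condition
#' A. Outputs are deterministic for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `linc_sim`: `spec`, `genome` (`DNAStringSet`),
#'   `reference` ([annotation_set()]), `transcripts` (novel transcript
#'   `GRangesList`, strand `*`), `truth` (data.frame per emitted transcript:
#'   `transcript_id`, `base_id`, `class`, `is_lincRNA_truth`,
#'   `planted_log2FC`, `planted_mean`), `counts` (data.frame
#'   `transcript_id`, `count_a`, `count_b`), `proteins` (`AAStringSet`),
#'   `mrnas`, `cds`, `training_noncoding` (`DNAStringSet`s) and `term_map`
#'   (toy gene-to-term table over the coding genes).
#' @export
simulate_lincrna_data <- function(spec = synthetic_spec()) {
  stopifnot(is(spec, "synthetic_spec"))
  set.seed(spec$seed)
  weights <- codon_usage_weights()
  chrom_len <- setNames(rep(floor(spec$genome_length_nt / spec$n_chrom), spec$n_chrom),
                        paste0("chr", seq_len(spec$n_chrom)))
  placer <- new_placer(chrom_len)
  repl <- lapply(chrom_len, function(...) list(at = IRanges::IRanges(), seq = character(0)))

  put_seq <- function(chrom, at, pieces) {
    repl[[chrom]]$at <<- c(repl[[chrom]]$at, at)
    repl[[chrom]]$seq <<- c(repl[[chrom]]$seq, pieces)
  }

  genes <- list()   # per gene: exons (IRanges), chrom, strand, type, seq (spliced 5'->3')
  make_gene <- function(seq, k_exons, strand, type, id, place_at = NULL) {
    L <- nchar(seq)
    ex <- exon_lengths(L, k_exons)
    introns <- if (length(ex) > 1) sample(200:1500, length(ex) - 1L, replace = TRUE) else integer(0)
    glen <- L + sum(introns)
    slot <- if (is.null(place_at)) placer$place(glen) else place_at
    at <- gene_coords(slot$start, ex, introns)
    put_seq(slot$chrom, at, exon_pieces(seq, ex, strand))
    genes[[id]] <<- list(id = id, chrom = slot$chrom, strand = strand,
                         exons = at, type = type, seq = seq)
    id
  }

  # --- reference genes ---------------------------------------------------
  cds <- character(spec$n_coding); mrna <- character(spec$n_coding)
  utr3_len <- integer(spec$n_coding)
  for (i in seq_len(spec$n_coding)) {
    ncod <- sample(150:400, 1)
    cds[i] <- make_cds(ncod, weights)
    u5 <- random_dna(sample(60:250, 1))
    u3 <- random_dna(sample(250:600, 1))
    utr3_len[i] <- nchar(u3)
    mrna[i] <- paste0(u5, cds[i], u3)
    make_gene(mrna[i], sample(2:6, 1), sample(c("+", "-"), 1),
              "protein_coding", sprintf("CG%03d", i))
  }
  for (i in seq_len(spec$n_known_lnc)) {
    s <- make_noncoding_seq(sample(500:2000, 1))
    make_gene(s, sample(2:5, 1), sample(c("+", "-"), 1),
              "lncRNA", sprintf("LNC%03d", i))
  }
  for (i in seq_len(spec$n_other_nc)) {
    make_gene(random_dna(sample(80:150, 1)), 1L, sample(c("+", "-"), 1),
              "other_ncRNA", sprintf("SRNA%03d", i))
  }

  coding_ids <- sprintf("CG%03d", seq_len(spec$n_coding))
  lnc_ids <- sprintf("LNC%03d", seq_len(spec$n_known_lnc))
  multi_coding <- coding_ids[vapply(coding_ids, function(g) length(genes[[g]]$exons) >= 2, logical(1))]
  lnc3 <- lnc_ids[vapply(lnc_ids, function(g) length(genes[[g]]$exons) >= 3, logical(1))]

  # --- novel transcript models (strand unknown) --------------------------
  novel <- list()  # per base transcript: chrom, exons (IRanges), class
  add_novel <- function(chrom, exons, class, id) {
    novel[[id]] <<- list(chrom = chrom, exons = exons, class = class)
  }
  nn <- spec$n_novel
  for (i in seq_len(nn[["full_coding"]])) {
    g <- genes[[sample(multi_coding, 1)]]
    add_novel(g$chrom, jitter_ends(g$exons, spec$end_jitter_nt),
              "full_coding", sprintf("novFC%03d", i))
  }
  for (i in seq_len(nn[["utr_fragment"]])) {
    g <- genes[[sample(coding_ids[utr3_len >= 320], 1)]]
    u3 <- utr3_len[match(g$id, coding_ids)]
    m <- sample(220:min(500, u3 - 20), 1)
    add_novel(g$chrom, spliced_tail_region(g$exons, g$strand, m),
              "utr_fragment", sprintf("novUTR%03d", i))
  }
  for (i in seq_len(nn[["intronic"]])) {
    repeat {
      g <- genes[[sample(multi_coding, 1)]]
      gaps <- IRanges::gaps(g$exons)
      gaps <- gaps[IRanges::width(gaps) >= 700]
      if (length(gaps)) break
    }
    gi <- gaps[sample.int(length(gaps), 1)]
    w <- sample(250:min(600, IRanges::width(gi) - 100), 1)
    st <- start(gi) + sample.int(IRanges::width(gi) - w - 99L, 1) + 49L
    add_novel(g$chrom, IRanges::IRanges(st, width = w),
              "intronic", sprintf("novINT%03d", i))
  }
  for (i in seq_len(nn[["antisense_like"]])) {
    g <- genes[[sample(coding_ids, 1)]]
    wide <- which(IRanges::width(g$exons) >= 80)
    if (length(wide) >= 2) {
      e1 <- g$exons[wide[1]]; e2 <- g$exons[wide[length(wide)]]
      ex <- IRanges::IRanges(c(start(e1) + 5L, start(e2) + 5L),
                             width = c(IRanges::width(e1) - 10L,
                                       IRanges::width(e2) - 10L))
    } else {
      e1 <- g$exons[which.max(IRanges::width(g$exons))]
      ex <- IRanges::IRanges(start(e1) + 5L, width = IRanges::width(e1) - 10L)
    }
    nv <- list(chrom = g$chrom, exons = ex, class = "antisense_like",
               strand = ifelse(g$strand == "+", "-", "+"))
    novel[[sprintf("novAS%03d", i)]] <- nv
  }
  n_im <- nn[["intergenic_multiexon"]]
  n_copy <- n_im %/% 3L; n_iso <- n_im %/% 3L; n_new <- n_im - n_copy - n_iso
  for (i in seq_len(n_copy)) {
    g <- genes[[sample(lnc_ids, 1)]]
    add_novel(g$chrom, g$exons, "intergenic_multiexon", sprintf("novLC%03d", i))
  }
  for (i in seq_len(n_iso)) {
    g <- genes[[sample(lnc3, 1)]]
    add_novel(g$chrom, g$exons[-1], "intergenic_multiexon", sprintf("novLI%03d", i))
  }
  for (i in seq_len(n_new)) {
    s <- make_noncoding_seq(sample(400:1500, 1))
    id <- make_gene(s, sample(2:4, 1), "+", "novel_linc", sprintf("NLOC%03d", i))
    g <- genes[[id]]
    add_novel(g$chrom, g$exons, "intergenic_multiexon", sprintf("novLN%03d", i))
    genes[[id]] <- NULL  # not part of the reference annotation
  }
  for (i in seq_len(nn[["intergenic_monoexon"]])) {
    s <- make_noncoding_seq(sample(250:800, 1))
    id <- make_gene(s, 1L, "+", "novel_mono", sprintf("NMON%03d", i))
    g <- genes[[id]]
    add_novel(g$chrom, g$exons, "intergenic_monoexon", sprintf("novLM%03d", i))
    genes[[id]] <- NULL
  }

  # --- assemble genome ----------------------------------------------------
  genome <- Biostrings::DNAStringSet(lapply(names(chrom_len), function(ch) {
    bg <- Biostrings::DNAString(random_dna(chrom_len[[ch]]))
    if (length(repl[[ch]]$at)) {
      bg <- Biostrings::replaceAt(bg, repl[[ch]]$at,
                                  Biostrings::DNAStringSet(repl[[ch]]$seq))
    }
    bg
  }))
  names(genome) <- names(chrom_len)

  # --- reference annotation ----------------------------------------------
  ref_ex <- exon_table_to_granges(lapply(genes, function(g) {
    data.frame(chrom = g$chrom, start = start(g$exons), end = end(g$exons),
               strand = g$strand, transcript_id = paste0(g$id, ".t1"),
               gene_id = g$id)
  }))
  biotype <- setNames(vapply(genes, function(g) g$type, character(1)),
                      vapply(genes, function(g) g$id, character(1)))
  reference <- annotation_set(transcript_models(ref_ex), biotype)

  # --- emit novel transcripts with redundant end-jittered copies ----------
  tx_rows <- list(); truth_rows <- list()
  for (id in names(novel)) {
    nv <- novel[[id]]
    strand_chr <- if (!is.null(nv$strand)) nv$strand else "*"
    copies <- c(id, if (spec$redundancy > 1)
      sprintf("%s_d%d", id, seq_len(spec$redundancy - 1L)))
    for (k in seq_along(copies)) {
      ex <- if (k == 1) nv$exons else jitter_ends(nv$exons, spec$end_jitter_nt)
      tx_rows[[copies[k]]] <- data.frame(
        chrom = nv$chrom, start = start(ex), end = end(ex),
        strand = strand_chr, transcript_id = copies[k], gene_id = NA_character_)
      truth_rows[[copies[k]]] <- data.frame(
        transcript_id = copies[k], base_id = id, class = nv$class,
        is_lincRNA_truth = nv$class == "intergenic_multiexon")
    }
  }
  transcripts <- transcript_models(exon_table_to_granges(tx_rows))
  truth <- do.call(rbind, unname(truth_rows))

  # --- planted expression and two-condition counts ------------------------
  is_coding_like <- truth$class %in% c("full_coding", "utr_fragment")
  mu_raw <- exp(rnorm(nrow(truth), mean = ifelse(is_coding_like, log(40), log(12)),
                      sd = 0.6))
  base_ids <- unique(truth$base_id)
  de_bases <- sample(base_ids, round(spec$de_fraction * length(base_ids)))
  truth$planted_log2FC <- ifelse(truth$base_id %in% de_bases, log2(spec$de_fold), 0)
  mean_b <- mu_raw * spec$depth / sum(mu_raw)
  mean_a <- mean_b * ifelse(truth$planted_log2FC != 0, spec$de_fold, 1)
  truth$planted_mean <- mean_b
  size <- 1 / spec$nb_dispersion
  counts <- data.frame(
    transcript_id = truth$transcript_id,
    count_a = rnbinom(nrow(truth), mu = mean_a, size = size),
    count_b = rnbinom(nrow(truth), mu = mean_b, size = size))

  # toy functional-term table over the coding genes
  terms <- sprintf("T%02d", 1:15)
  term_map <- do.call(rbind, lapply(coding_ids, function(g) {
    data.frame(gene_id = g, term_id = sample(terms, sample(1:3, 1)))
  }))

  structure(list(spec = spec, genome = genome, reference = reference,
                 transcripts = transcripts, truth = truth, counts = counts,
                 proteins = translate_cds(cds, coding_ids),
                 mrnas = setNames(Biostrings::DNAStringSet(mrna),
                                  paste0(coding_ids, ".t1")),
                 cds = setNames(Biostrings::DNAStringSet(cds),
                                paste0(coding_ids, ".cds")),
                 training_noncoding = training_noncoding_set(spec),
                 term_map = term_map),
            class = "linc_sim")
}

exon_table_to_granges <- function(rows) {
  df <- do.call(rbind, unname(rows))
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand, transcript_id = df$transcript_id,
                         gene_id = df$gene_id)
}

translate_cds <- function(cds, ids) {
  aa <- Biostrings::translate(Biostrings::DNAStringSet(cds))
  aa <- Biostrings::AAStringSet(sub("\\*$", "", as.character(aa)))
  names(aa) <- paste0(ids, ".p1")
  aa
}

training_noncoding_set <- function(spec) {
  s <- vapply(seq_len(spec$n_train_noncoding), function(i)
    make_noncoding_seq(sample(300:2000, 1)), character(1))
  setNames(Biostrings::DNAStringSet(s),
           sprintf("NCTRAIN%03d", seq_len(spec$n_train_noncoding)))
}

#' @export
print.linc_sim <- function(x, ...) {
  cat("linc_sim: genome", sum(Biostrings::width(x$genome)), "nt,",
      length(x$reference$genes), "reference genes,",
      length(x$transcripts), "novel transcript models (",
      sum(x$truth$is_lincRNA_truth), "planted lincRNAs )\n")
  invisible(x)
}

#' Write a simulation to disk as plain-text files
#'
#' Emits `genome.fa`, `reference.gtf`, `transcripts.gtf`, `proteins.fa`,
#' `mrnas.fa`, `truth.tsv` and `counts_a.tsv` / `counts_b.tsv` into `dir`.
#'
#' @param sim a [simulate_lincrna_data()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_annotation_gtf(sim$reference, file.path(dir, "reference.gtf"))
  write_transcript_gtf(sim$transcripts, file.path(dir, "transcripts.gtf"))
  Biostrings::writeXStringSet(sim$proteins, file.path(dir, "proteins.fa"))
  Biostrings::writeXStringSet(sim$mrnas, file.path(dir, "mrnas.fa"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cond in c("a", "b")) {
    df <- data.frame(transcript_id = sim$counts$transcript_id,
                     count = sim$counts[[paste0("count_", cond)]])
    write.table(df, file.path(dir, paste0("counts_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
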