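#' Compare transcript exon chains against a reference annotation
#'
#' For each transcript the best-matching reference transcript is found and a
#' match score, an intron-sharing flag and a one-character class code are
#' assigned:
#'
#' * score 5 - identical intron chain and both outer ends within
#'   `end_tolerance_nt` (a perfect structural match; for single-exon models,
#'   exon overlap with a single-exon reference plus ends within tolerance);
#' * score 4 - identical intron chain, ends beyond tolerance;
#' * score 3 - the transcript's intron chain is a contiguous subchain of a
#'   reference chain;
#' * score 2 - at least one shared splice junction;
#' * score 1 - exon overlap only; score 0 - no overlap.
#'
#' Scores below 5 are internal diagnostics; only score 5 has filtering
#' consequences downstream. Class codes follow the cuffcompare-style
#' decision tree: `=` identical chain; `c` contained subchain within the
#' reference boundaries; `j` shared junction with a different chain; `x`
#' exon overlap on the opposite (known) strand; `i` within a reference gene
#' but touching no reference exon (intronic); `o` generic exon overlap;
#' `u` no exon overlaps any reference gene span (intergenic). `shares_intron`
#' is `TRUE` iff any intron of the transcript coincides exactly with an
#' intron of a protein-coding reference transcript.
#'
#' @param tx transcript `GRangesList`.
#' @param ref an [annotation_set()].
#' @param end_tolerance_nt terminal-end tolerance for score 5 (nt).
#' @return data.frame: `transcript_id`, `best_ref_transcript`, `match_score`,
#'   `shares_intron`, `class_code`.
#' @export
classify_transcripts <- function(tx, ref, end_tolerance_nt = 100L) {
  ref_tx <- ref$transcripts
  ref_key <- intron_chain_key(ref_tx)
  ref_introns <- introns_of(ref_tx)
  ref_span <- transcript_span(ref_tx)
  ref_nex <- n_exons(ref_tx)
  ref_strand <- as.character(unlist(unique(GenomicRanges::strand(ref_tx)), use.names = FALSE))
  ref_gene <- ref$tx2gene[names(ref_tx)]
  ref_bt <- setNames(ref$genes$biotype, names(ref$genes))[ref_gene]
  coding_intron_keys <- unique(unlist(lapply(which(ref_bt == "protein_coding"), function(i) {
    g <- ref_introns[[i]]
    if (!length(g)) return(character(0))
    paste0(as.character(GenomicRanges::seqnames(ref_span))[i], ":", start(g), "-", end(g))
  })))
  ref_exons_flat <- unlist(ref_tx, use.names = FALSE)
  ref_exons_flat$tx_idx <- rep(seq_along(ref_tx), S4Vectors::elementNROWS(ref_tx))

  span <- transcript_span(tx)
  tx_strand <- as.character(unlist(unique(GenomicRanges::strand(tx)), use.names = FALSE))
  tx_chrom <- as.character(GenomicRanges::seqnames(span))
  gene_hits <- GenomicRanges::findOverlaps(tx, ref$genes, ignore.strand = TRUE)
  span_hits <- GenomicRanges::findOverlaps(span, ref_span, ignore.strand = TRUE)
  exon_ov <- GenomicRanges::findOverlaps(tx, ref_tx, ignore.strand = TRUE)

  n <- length(tx)
  best_ref <- rep(NA_character_, n)
  score <- integer(n)
  class_code <- rep("u", n)
  shares <- logical(n)

  tx_introns <- introns_of(tx)
  tx_key <- intron_chain_key(tx)

  for (i in seq_len(n)) {
    my_introns <- tx_introns[[i]]
    if (length(my_introns)) {
      keys <- paste0(tx_chrom[i], ":", start(my_introns), "-", end(my_introns))
      shares[i] <- any(keys %in% coding_intron_keys)
    }
    overlapped_genes <- S4Vectors::subjectHits(gene_hits)[S4Vectors::queryHits(gene_hits) == i]
    if (!length(overlapped_genes)) { class_code[i] <- "u"; score[i] <- 0L; next }

    cand <- S4Vectors::subjectHits(span_hits)[S4Vectors::queryHits(span_hits) == i]
    exon_cand <- S4Vectors::subjectHits(exon_ov)[S4Vectors::queryHits(exon_ov) == i]
    best_s <- 0L; best_j <- NA_integer_; best_cls <- NA_character_
    for (j in cand) {
      s <- 0L; cls <- NA_character_
      same_chain <- chains_identical(i, j, tx, ref_tx, tx_key, ref_key,
                                     span, ref_span, ref_nex)
      if (same_chain) {
        ends_ok <- abs(start(span)[i] - start(ref_span)[j]) <= end_tolerance_nt &&
          abs(end(span)[i] - end(ref_span)[j]) <= end_tolerance_nt
        s <- if (ends_ok) 5L else 4L
        cls <- "="
      } else if (length(my_introns) &&
                 is_contiguous_subchain(my_introns, ref_introns[[j]])) {
        s <- 3L
        cls <- if (start(span)[i] >= start(ref_span)[j] &&
                   end(span)[i] <= end(ref_span)[j]) "c" else "j"
      } else {
        shared_j <- if (length(my_introns) && length(ref_introns[[j]]))
          sum(paste(start(my_introns), end(my_introns)) %in%
                paste(start(ref_introns[[j]]), end(ref_introns[[j]]))) else 0L
        if (shared_j > 0) { s <- 2L; cls <- "j" }
        else if (j %in% exon_cand) {
          s <- 1L
          cls <- if (tx_strand[i] != "*" && ref_strand[j] != "*" &&
                     tx_strand[i] != ref_strand[j]) "x"
                 else if (n_exons(tx)[i] == 1 && length(exon_containing(tx[[i]], ref_tx[[j]]))) "c"
                 else "o"
        } else { s <- 0L; cls <- "i" }  # within span, touches no exon
      }
      if (s > best_s || (s == best_s && is.na(best_j))) {
        best_s <- s; best_j <- j; best_cls <- cls
      }
    }
    if (is.na(best_j)) {
      # overlaps a gene span but no transcript span of it (possible when a
      # gene hull spans more than its transcripts); treat as intronic
      class_code[i] <- "i"; score[i] <- 0L
    } else {
      score[i] <- best_s
      class_code[i] <- best_cls
      best_ref[i] <- names(ref_tx)[best_j]
    }
  }
  data.frame(transcript_id = names(tx), best_ref_transcript = best_ref,
             match_score = score, shares_intron = shares, class_code = class_code)
}

chains_identical <- function(i, j, tx, ref_tx, tx_key, ref_key, span, ref_span, ref_nex) {
  ki <- tx_key[i]; kj <- ref_key[j]
  if (!is.na(ki) && !is.na(kj)) return(ki == kj)
  if (is.na(ki) && is.na(kj)) {
    # both single-exon: identical chain trivially, require exon overlap
    return(overlap_bp(span[i], ref_span[j]) > 0)
  }
  FALSE
}

is_contiguous_subchain <- function(sub, full) {
  if (!length(full) || length(sub) > length(full)) return(FALSE)
  sub_k <- paste(start(sub), end(sub))
  full_k <- paste(start(full), end(full))
  idx <- match(sub_k, full_k)
  if (anyNA(idx)) return(FALSE)
  all(diff(idx) == 1L)
}

exon_containing <- function(tx_exons, ref_exons) {
  which(start(ref_exons) <= min(start(tx_exons)) &
          end(ref_exons) >= max(end(tx_exons)))
}

#' Select multi-exon intergenic lncRNAs (lincRNAs)
#'
#' Applies the structural filters to candidates that already survived the
#' coding filters: transcripts perfectly matching (score 5) a
#' protein-coding or structural-RNA gene are removed; transcripts sharing
#' any intron with a protein-coding gene are removed; of the remainder,
#' only class-`u` (no exon overlap with any reference gene span), multi-exon
#' transcripts are called lincRNAs. Called lincRNAs are clustered into loci
#' (see [cluster_loci()]) and, when a lncRNA annotation is supplied, tiered
#' by novelty: identical structure to a known lncRNA (`known_structure`),
#' exon overlap with a known lncRNA locus (`novel_isoform_of_known_locus`),
#' or neither (`novel_locus`).
#'
#' @param tx transcript `GRangesList` of candidates.
#' @param matches result of [classify_transcripts()] for `tx` against the
#'   protein-coding/structural-RNA reference.
#' @param ref the [annotation_set()] used for `matches` (provides biotypes).
#' @param lnc_ref optional [annotation_set()] of known lncRNA genes.
#' @param end_tolerance_nt tolerance used for novelty structure matching.
#' @return data.frame: `transcript_id`, `is_lincRNA`, `drop_reason` (`NA`,
#'   `perfect_structure_match`, `shares_coding_intron`, `overlaps_known_gene`,
#'   `single_exon`), `n_exons`, `class_code`, `novelty`, `locus_id`.
#' @export
select_lincRNAs <- function(tx, matches, ref, lnc_ref = NULL,
                            end_tolerance_nt = 100L) {
  stopifnot(identical(matches$transcript_id, names(tx)))
  nx <- n_exons(tx)
  reason <- rep(NA_character_, length(tx))
  ref_gene <- ref$tx2gene
  ref_bt <- setNames(ref$genes$biotype, names(ref$genes))
  best_bt <- ref_bt[ref_gene[matches$best_ref_transcript]]
  perfect <- matches$match_score == 5 &
    !is.na(best_bt) & best_bt %in% c("protein_coding", "other_ncRNA")
  reason[perfect] <- "perfect_structure_match"
  sel <- is.na(reason) & matches$shares_intron
  reason[sel] <- "shares_coding_intron"
  sel <- is.na(reason) & matches$class_code != "u"
  reason[sel] <- "overlaps_known_gene"
  sel <- is.na(reason) & nx < 2
  reason[sel] <- "single_exon"
  is_linc <- is.na(reason)

  novelty <- rep(NA_character_, length(tx))
  locus <- rep(NA_character_, length(tx))
  if (any(is_linc)) {
    linc_tx <- tx[is_linc]
    locus[is_linc] <- cluster_loci(linc_tx)
    if (!is.null(lnc_ref) && length(lnc_ref$transcripts)) {
      lm <- classify_transcripts(linc_tx, lnc_ref, end_tolerance_nt)
      nv <- ifelse(lm$class_code == "=", "known_structure",
                   ifelse(lm$class_code == "u", "novel_locus",
                          "novel_isoform_of_known_locus"))
      # class i means inside a known lncRNA locus without touching exons:
      # still an overlap at locus level
      nv[lm$class_code == "i"] <- "novel_isoform_of_known_locus"
      novelty[is_linc] <- nv
    } else {
      novelty[is_linc] <- "novel_locus"
    }
  }
  data.frame(transcript_id = names(tx), is_lincRNA = is_linc,
             drop_reason = reason, n_exons = unname(nx),
             class_code = matches$class_code, novelty = novelty,
             locus_id = locus)
}

#' Cluster transcripts into loci by exon overlap
#'
#' Single-linkage clustering: two transcripts belong to the same locus iff
#' they are connected through pairs sharing at least 1 bp of exon overlap on
#' the same chromosome. Strand is ignored (long-read models may have unknown
#' strand). Locus ids are deterministic, ordered by (chromosome, locus
#' start).
#'
#' @param tx transcript `GRangesList`.
#' @return character vector of locus ids (`XLOC_000001`, ...), parallel to
#'   `tx`.
#' @export
cluster_loci <- function(tx) {
  if (!length(tx)) return(character(0))
  ov <- GenomicRanges::findOverlaps(tx, tx, ignore.strand = TRUE)
  ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
  comp <- components_from_edges(length(tx),
                                cbind(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov)))
  span <- transcript_span(tx)
  comp_chrom <- tapply(as.character(GenomicRanges::seqnames(span)), comp, min)
  comp_start <- tapply(start(span), comp, min)
  ord <- order(comp_chrom, comp_start)
  rank <- match(seq_along(ord), ord)
  sprintf("XLOC_%06d", rank[comp])
}

#' Compare two transcript annotations structure-wise
#'
#' Each transcript of `setA` is labelled `same_structure` when it has an
#' identical intron chain in `setB` (single-exon: overlapping single-exon
#' counterpart), `overlap_only` when it shares exonic sequence with some
#' `setB` transcript without an identical chain, and `absent` otherwise.
#'
#' @param setA,setB transcript `GRangesList`s on the same genome build.
#' @return data.frame `transcript_id`, `status`.
#' @export
compare_annotations <- function(setA, setB) {
  ann_b <- annotation_set(setB)
  m <- classify_transcripts(setA, ann_b)
  exon_overlap <- IRanges::overlapsAny(setA, setB, ignore.strand = TRUE)
  status <- ifelse(m$class_code == "=", "same_structure",
                   ifelse(exon_overlap, "overlap_only", "absent"))
  data.frame(transcript_id = names(setA), status = status)
}
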