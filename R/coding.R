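#' Coding-potential features of nucleotide sequences
#'
#' For each sequence (one orientation) computes the four classic logistic
#' features: longest ORF length (nt), ORF coverage (longest ORF length over
#' sequence length), Fickett TESTCODE score, and mean in-frame hexamer
#' log-likelihood ratio of the longest ORF.
#'
#' @param seqs `DNAStringSet` or character vector (named).
#' @param hexamer_table a [train_hexamer_table()] result.
#' @return data.frame with columns `id`, `length_nt`, `orf_length_nt`,
#'   `orf_coverage`, `fickett_score`, `hexamer_score`.
#' @export
coding_features <- function(seqs, hexamer_table) {
  seqs <- as_dss(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  ch <- as.character(seqs)
  rows <- lapply(seq_along(ch), function(i) {
    orf <- longest_orf(ch[i])
    L <- nchar(ch[i])
    data.frame(id = ids[i], length_nt = L,
               orf_length_nt = orf$length_nt,
               orf_coverage = if (L > 0) orf$length_nt / L else 0,
               fickett_score = suppressWarnings(fickett_testcode(ch[i])),
               hexamer_score = if (orf$length_nt >= 6)
                 hexamer_bias(orf$seq, hexamer_table) else 0)
  })
  do.call(rbind, rows)
}

#' Train the logistic coding-probability model
#'
#' Plain logistic regression (IRLS via [stats::glm()], convergence tolerance
#' 1e-8) of the coding/noncoding label on the four features of
#' [coding_features()]. On cleanly separable training data the fit reports
#' quasi-separation; the fitted probabilities are still well defined and the
#' warning is suppressed.
#'
#' @param coding,noncoding `DNAStringSet` of labelled training transcripts
#'   (full transcripts; the hexamer table is typically trained on CDS).
#' @param hexamer_table a [train_hexamer_table()] result; if `NULL`, trained
#'   on the fly from `coding` vs `noncoding`.
#' @return object of class `coding_model`: list with the fitted `glm`, the
#'   hexamer table and the feature names.
#' @export
train_coding_model <- function(coding, noncoding, hexamer_table = NULL) {
  coding <- as_dss(coding); noncoding <- as_dss(noncoding)
  if (is.null(hexamer_table)) hexamer_table <- train_hexamer_table(coding, noncoding)
  feats <- rbind(cbind(coding_features(coding, hexamer_table), label = 1),
                 cbind(coding_features(noncoding, hexamer_table), label = 0))
  fit <- suppressWarnings(
    glm(label ~ orf_length_nt + orf_coverage + fickett_score + hexamer_score,
        family = binomial(), data = feats,
        control = list(epsilon = 1e-8, maxit = 100)))
  structure(list(fit = fit, hexamer_table = hexamer_table,
                 features = c("orf_length_nt", "orf_coverage",
                              "fickett_score", "hexamer_score")),
            class = "coding_model")
}

#' Logistic coding probability from precomputed features
#'
#' `p = 1 / (1 + exp(-(b0 + b1*orf_length + b2*orf_coverage + b3*fickett +
#' b4*hexamer)))`. `model` may be a `coding_model` or a bare numeric vector
#' of five coefficients (intercept first), which supports hand-specified
#' weights.
#'
#' @param features data.frame from [coding_features()].
#' @param model a `coding_model` or numeric coefficient vector of length 5.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
coding_probability <- function(features, model) {
  if (is.numeric(model)) {
    stopifnot(length(model) == 5)
    eta <- model[1] + model[2] * features$orf_length_nt +
      model[3] * features$orf_coverage + model[4] * features$fickett_score +
      model[5] * features$hexamer_score
    return(1 / (1 + exp(-eta)))
  }
  if (!is(model, "coding_model")) stop("model must be a coding_model or 5 coefficients")
  as.numeric(predict(model$fit, newdata = features, type = "response"))
}

#' Assess coding potential of transcript sequences
#'
#' Computes features and coding probability per transcript. For transcripts
#' whose strand is unknown (flagged in `both_strands`, see
#' [spliced_sequence()]), features are computed for both orientations and
#' the reported probability is the maximum of the two, with the features of
#' the higher-scoring orientation retained.
#'
#' @param seqs `DNAStringSet` of spliced transcript sequences; a logical
#'   `both_strands` metadata column (or the `both_strands` argument) marks
#'   strand-unknown transcripts.
#' @param model a `coding_model` (see [train_coding_model()]).
#' @param both_strands logical vector overriding the metadata flag.
#' @param cutoff coding-probability threshold; a transcript is called coding
#'   iff its probability strictly exceeds the cutoff (default 0.44).
#' @return data.frame (one row per transcript): `transcript_id`, the four
#'   features, `orientation` (`+`/`-` of the scored orientation),
#'   `coding_probability`, `verdict` (`coding` / `noncoding_candidate`).
#' @export
assess_coding <- function(seqs, model, both_strands = NULL, cutoff = 0.44) {
  seqs <- as_dss(seqs)
  if (is.null(both_strands)) {
    both_strands <- S4Vectors::mcols(seqs)$both_strands
    if (is.null(both_strands)) both_strands <- rep(FALSE, length(seqs))
  }
  fwd <- coding_features(seqs, model$hexamer_table)
  p_fwd <- coding_probability(fwd, model)
  out <- fwd
  out$orientation <- "+"
  out$coding_probability <- p_fwd
  if (any(both_strands)) {
    rc <- Biostrings::reverseComplement(seqs[both_strands])
    rev_feats <- coding_features(rc, model$hexamer_table)
    p_rev <- coding_probability(rev_feats, model)
    idx <- which(both_strands)
    take <- p_rev > p_fwd[idx]
    if (any(take)) {
      cols <- c("orf_length_nt", "orf_coverage", "fickett_score", "hexamer_score")
      out[idx[take], cols] <- rev_feats[take, cols]
      out[idx[take], "coding_probability"] <- p_rev[take]
      out[idx[take], "orientation"] <- "-"
    }
  }
  names(out)[names(out) == "id"] <- "transcript_id"
  out$verdict <- ifelse(out$coding_probability > cutoff,
                        "coding", "noncoding_candidate")
  out
}

#' Coding-filter parameters
#'
#' All thresholds implement strict inequalities: a transcript is dropped
#' when its coding probability is strictly greater than `cutoff`, when a
#' long-ORF peptide is strictly more than `pep_identity` identical to a
#' known protein over an alignment strictly longer than `pep_min_len` amino
#' acids, and when a transcript aligns to a known mRNA at strictly more than
#' `nuc_identity` identity over strictly more than `nuc_coverage` of its
#' length. `min_orf_aa` gates which ORFs are subject to the protein filters
#' (peptides strictly longer than 100 aa).
#'
#' @param cutoff coding-probability cutoff (default 0.44).
#' @param min_orf_aa peptide-length gate for the homology/domain filters.
#' @param pep_identity,pep_min_len protein-homology thresholds.
#' @param nuc_identity,nuc_coverage mRNA-homology (UTR fragment) thresholds.
#' @return list of class `coding_filter_params`.
#' @export
coding_filter_params <- function(cutoff = 0.44, min_orf_aa = 100L,
                                 pep_identity = 0.85, pep_min_len = 50L,
                                 nuc_identity = 0.95, nuc_coverage = 0.50) {
  structure(list(cutoff = cutoff, min_orf_aa = as.integer(min_orf_aa),
                 pep_identity = pep_identity, pep_min_len = as.integer(pep_min_len),
                 nuc_identity = nuc_identity, nuc_coverage = nuc_coverage),
            class = "coding_filter_params")
}

#' Apply the ordered coding filters
#'
#' Rules are evaluated in order and the first failing rule is recorded:
#' 1. `coding_probability`: probability strictly above the cutoff;
#' 2. `orf_homology`: any ORF peptide longer than `min_orf_aa` with a
#'    protein hit of identity > `pep_identity` over > `pep_min_len` aligned
#'    amino acids;
#' 3. `orf_domain`: any domain hit recorded for the transcript (domain
#'    scanning itself is ingested as a table, not performed here);
#' 4. `utr_fragment`: an mRNA hit with identity > `nuc_identity` covering
#'    > `nuc_coverage` of the transcript length.
#'
#' @param assessment data.frame from [assess_coding()].
#' @param protein_hits data.frame of protein alignments with columns
#'   `transcript_id`, `peptide_length`, `identity` (fraction),
#'   `alignment_length` (aa); see [protein_homology_hits()]. May be `NULL`.
#' @param nucleotide_hits data.frame with columns `transcript_id`,
#'   `identity`, `query_coverage`; see [transcript_mrna_hits()]. May be `NULL`.
#' @param domain_hits data.frame with a `transcript_id` column (one row per
#'   domain hit on a qualifying ORF). May be `NULL`.
#' @param params a [coding_filter_params()].
#' @return data.frame `transcript_id`, `keep` (logical), `reason` (`NA` for
#'   kept transcripts, else one of `coding_probability`, `orf_homology`,
#'   `orf_domain`, `utr_fragment`).
#' @export
apply_coding_filters <- function(assessment, protein_hits = NULL,
                                 nucleotide_hits = NULL, domain_hits = NULL,
                                 params = coding_filter_params()) {
  ids <- assessment$transcript_id
  reason <- rep(NA_character_, length(ids))

  drop_p <- assessment$coding_probability > params$cutoff
  reason[drop_p] <- "coding_probability"

  if (!is.null(protein_hits) && nrow(protein_hits)) {
    bad <- protein_hits$peptide_length > params$min_orf_aa &
      protein_hits$identity > params$pep_identity &
      protein_hits$alignment_length > params$pep_min_len
    hit_ids <- unique(protein_hits$transcript_id[bad])
    sel <- is.na(reason) & ids %in% hit_ids
    reason[sel] <- "orf_homology"
  }
  if (!is.null(domain_hits) && nrow(domain_hits)) {
    sel <- is.na(reason) & ids %in% unique(domain_hits$transcript_id)
    reason[sel] <- "orf_domain"
  }
  if (!is.null(nucleotide_hits) && nrow(nucleotide_hits)) {
    bad <- nucleotide_hits$identity > params$nuc_identity &
      nucleotide_hits$query_coverage > params$nuc_coverage
    hit_ids <- unique(nucleotide_hits$transcript_id[bad])
    sel <- is.na(reason) & ids %in% hit_ids
    reason[sel] <- "utr_fragment"
  }
  data.frame(transcript_id = ids, keep = is.na(reason), reason = reason)
}
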