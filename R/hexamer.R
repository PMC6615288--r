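#' Train a hexamer usage table
#'
#' Computes, for each of the 4096 hexamers, the log-likelihood ratio
#' `log((c_h + 1) / sum(c + 1)) - log((n_h + 1) / sum(n + 1))` between
#' in-frame hexamer counts of coding sequences (counted at step 3 in the CDS
#' frame) and sliding hexamer counts of noncoding sequences (step 1), with
#' add-one smoothing so every entry is finite.
#'
#' Because the two classes are counted with different steps, the table is
#' generally non-zero even for identical inputs; equal steps recover the
#' zero table in that degenerate case.
#'
#' @param coding `DNAStringSet` (or character vector) of in-frame coding
#'   sequences (CDS, frame 0).
#' @param noncoding `DNAStringSet` (or character) of noncoding sequences.
#' @param coding_step,noncoding_step counting strides (3 = in-frame,
#'   1 = sliding).
#' @return named numeric vector of length 4096 (class `hexamer_table`).
#' @export
train_hexamer_table <- function(coding, noncoding, coding_step = 3L,
                                noncoding_step = 1L) {
  coding <- as_dss(coding)
  noncoding <- as_dss(noncoding)
  if (length(coding) < 10 || length(noncoding) < 10) {
    stop("need at least 10 sequences per class to train a hexamer table")
  }
  c_cnt <- hexamer_counts(coding, step = coding_step)
  n_cnt <- hexamer_counts(noncoding, step = noncoding_step)
  tab <- log((c_cnt + 1) / sum(c_cnt + 1)) - log((n_cnt + 1) / sum(n_cnt + 1))
  structure(tab, class = "hexamer_table")
}

as_dss <- function(x) if (is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)

hexamer_counts <- function(seqs, step) {
  keep <- Biostrings::width(seqs) >= 6
  if (!any(keep)) return(setNames(numeric(4096), Biostrings::mkAllStrings(c("A","C","G","T"), 6)))
  m <- Biostrings::oligonucleotideFrequency(seqs[keep], width = 6, step = step)
  colSums(m)
}

#' Mean in-frame hexamer log-likelihood ratio of an ORF
#'
#' Steps through `orf_seq` three nucleotides at a time (the reading frame of
#' the ORF) and averages the table entries of the hexamers encountered.
#' Hexamers containing a base outside `A,C,G,T` are skipped; if no valid
#' hexamer remains the score is 0.
#'
#' @param orf_seq nucleotide string (the ORF, frame 0).
#' @param table a [train_hexamer_table()] result (or any named vector over
#'   the 4096 hexamers).
#' @return mean log-likelihood ratio (nats).
#' @export
hexamer_bias <- function(orf_seq, table) {
  orf_seq <- toupper(as.character(orf_seq))
  L <- nchar(orf_seq)
  if (L < 6) return(0)
  starts <- seq.int(1L, L - 5L, by = 3L)
  hx <- substring(orf_seq, starts, starts + 5L)
  vals <- unname(table[hx])
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}
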