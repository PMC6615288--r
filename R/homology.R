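#' Local-alignment hits of long-ORF peptides against known proteins
#'
#' Translates every ORF peptide strictly longer than `min_orf_aa` amino
#' acids and aligns it locally (Smith-Waterman, BLOSUM62, gap open 11,
#' extend 1 - mirroring BLASTP defaults) against each known protein.
#' Identity is matches over alignment columns (gaps included).
#'
#' @param seqs `DNAStringSet` of spliced transcript sequences (strand-unknown
#'   sequences are scanned on both strands for ORFs).
#' @param proteins `AAStringSet` of known proteins.
#' @param min_orf_aa only peptides strictly longer than this are aligned.
#' @param both_strands logical vector per transcript (defaults to the
#'   `both_strands` metadata of `seqs`, else `FALSE`).
#' @return data.frame with columns `transcript_id`, `peptide_length`,
#'   `protein_id`, `identity`, `alignment_length` (one row per ORF x protein
#'   with alignment length > 0).
#' @export
protein_homology_hits <- function(seqs, proteins, min_orf_aa = 100L,
                                  both_strands = NULL) {
  seqs <- as_dss(seqs)
  if (is.null(both_strands)) {
    both_strands <- S4Vectors::mcols(seqs)$both_strands
    if (is.null(both_strands)) both_strands <- rep(FALSE, length(seqs))
  }
  peps <- character(0); pep_tx <- character(0); pep_len <- integer(0)
  for (i in seq_along(seqs)) {
    ch <- as.character(seqs[[i]])
    orfs <- find_orfs(ch, both_strands = both_strands[i])
    orfs <- orfs[orfs$peptide_length > min_orf_aa, , drop = FALSE]
    if (!nrow(orfs)) next
    for (k in seq_len(nrow(orfs))) {
      s <- if (orfs$orf_strand[k] == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(ch)))
      else ch
      cds <- substring(s, orfs$start[k], orfs$end[k])
      ncod <- nchar(cds) %/% 3
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(substr(cds, 1, ncod * 3)),
                              if.fuzzy.codon = "solve")))
      aa <- sub("\\*$", "", aa)
      peps <- c(peps, aa); pep_tx <- c(pep_tx, names(seqs)[i])
      pep_len <- c(pep_len, nchar(aa))
    }
  }
  out <- data.frame(transcript_id = character(0), peptide_length = integer(0),
                    protein_id = character(0), identity = numeric(0),
                    alignment_length = integer(0))
  if (!length(peps) || !length(proteins)) return(out)
  pep_set <- Biostrings::AAStringSet(peps)
  for (j in seq_along(proteins)) {
    aln <- Biostrings::pairwiseAlignment(pep_set, proteins[[j]], type = "local",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 11, gapExtension = 1)
    len <- Biostrings::nchar(aln)
    ident <- ifelse(len > 0, Biostrings::nmatch(aln) / len, 0)
    keep <- len > 0
    if (any(keep)) {
      out <- rbind(out, data.frame(transcript_id = pep_tx[keep],
                                   peptide_length = pep_len[keep],
                                   protein_id = names(proteins)[j],
                                   identity = ident[keep],
                                   alignment_length = len[keep]))
    }
  }
  out
}

#' Local-alignment hits of transcripts against known mRNAs
#'
#' Emulates a BLASTN screen with an explicit seed-and-extend heuristic:
#' exact 24-mers sampled every 12 nt from the mRNA set act as seeds, and
#' only transcript/mRNA pairs sharing a seed (in either orientation) are
#' aligned with Smith-Waterman (match 1, mismatch -2, gap open 5, extend 2,
#' mirroring BLASTN defaults). Identity is matches over alignment columns;
#' `query_coverage` is the aligned transcript span over transcript length.
#'
#' @param seqs `DNAStringSet` of transcript sequences.
#' @param mrnas `DNAStringSet` of known mRNAs.
#' @param seed_width,seed_step seeding parameters.
#' @return data.frame `transcript_id`, `mrna_id`, `orientation`, `identity`,
#'   `query_coverage`.
#' @export
transcript_mrna_hits <- function(seqs, mrnas, seed_width = 24L, seed_step = 12L) {
  seqs <- as_dss(seqs); mrnas <- as_dss(mrnas)
  out <- data.frame(transcript_id = character(0), mrna_id = character(0),
                    orientation = character(0), identity = numeric(0),
                    query_coverage = numeric(0))
  if (!length(seqs) || !length(mrnas)) return(out)
  seeds <- list(); seed_src <- integer(0)
  for (j in seq_along(mrnas)) {
    L <- Biostrings::width(mrnas)[j]
    if (L < seed_width) next
    st <- unique(c(seq.int(1L, L - seed_width + 1L, by = seed_step),
                   L - seed_width + 1L))
    seeds[[length(seeds) + 1L]] <-
      Biostrings::extractAt(mrnas[[j]], IRanges::IRanges(st, width = seed_width))
    seed_src <- c(seed_src, rep(j, length(st)))
  }
  if (!length(seeds)) return(out)
  seed_set <- do.call(c, seeds)
  pd <- Biostrings::PDict(seed_set)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in seq_along(seqs)) {
    for (ori in c("+", "-")) {
      q <- if (ori == "+") seqs[[i]] else Biostrings::reverseComplement(seqs[[i]])
      hit_mrna <- unique(seed_src[Biostrings::whichPDict(pd, q)])
      for (j in hit_mrna) {
        aln <- Biostrings::pairwiseAlignment(q, mrnas[[j]], type = "local",
                                             substitutionMatrix = submat,
                                             gapOpening = 5, gapExtension = 2)
        len <- Biostrings::nchar(aln)
        if (len == 0) next
        qspan <- Biostrings::width(Biostrings::pattern(aln))
        out <- rbind(out, data.frame(
          transcript_id = names(seqs)[i], mrna_id = names(mrnas)[j],
          orientation = ori,
          identity = Biostrings::nmatch(aln) / len,
          query_coverage = qspan / Biostrings::width(seqs)[i]))
      }
    }
  }
  out
}

#' Read a precomputed protein-domain hit table
#'
#' Tab-separated table with at least a `transcript_id` column (typically
#' `transcript_id`, `orf_id`, `domain_accession`, `score`), as produced by an
#' external profile-HMM scan. Any row for a transcript marks it as
#' domain-positive for [apply_coding_filters()].
#'
#' @param path TSV file with a header.
#' @return data.frame.
#' @export
read_domain_hits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"transcript_id" %in% names(df)) stop("domain table needs a transcript_id column")
  df
}
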