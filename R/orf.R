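STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find ATG-initiated open reading frames
#'
#' Scans all three frames (and, optionally, the reverse complement) for ORFs
#' starting at an ATG and running to the first in-frame stop codon, or to the
#' end of the sequence if no stop follows (reported with `has_stop = FALSE`).
#' Every ATG yields an ORF, so nested in-frame ORFs sharing a stop are all
#' reported. Codons containing `N` are treated as neither start nor stop.
#'
#' @param seq a single nucleotide string (character or `DNAString`) over
#'   `A,C,G,T,N`.
#' @param both_strands also scan the reverse complement.
#' @return data.frame sorted by decreasing peptide length with columns
#'   `orf_strand` (`+` = as-given orientation, `-` = reverse complement),
#'   `frame` (0-2), `start`, `end` (1-based inclusive offsets in the scanned
#'   orientation, `end` includes the stop codon when present), `has_stop`,
#'   `orf_length_nt` (`end - start + 1`) and `peptide_length` (amino acids,
#'   stop excluded).
#' @examples
#' find_orfs("ATGAAATAG")   # one ORF, 2 aa
#' find_orfs("CCCCCC")      # none
#' @export
find_orfs <- function(seq, both_strands = FALSE) {
  seq <- toupper(as.character(seq))
  res <- orf_scan_one(seq, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    res <- rbind(res, orf_scan_one(rc, "-"))
  }
  res[order(-res$peptide_length, res$orf_strand, res$start), , drop = FALSE]
}

orf_scan_one <- function(seq, strand_label) {
  L <- nchar(seq)
  empty <- data.frame(orf_strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      has_stop = logical(0), orf_length_nt = integer(0),
                      peptide_length = integer(0))
  if (L < 3) return(empty)
  out <- empty
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, L - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% STOP_CODONS)
    # index of first stop at or after each ATG
    nxt <- findInterval(atg - 0.5, stops) + 1L
    for (k in seq_along(atg)) {
      i <- atg[k]
      j <- if (nxt[k] <= length(stops)) stops[nxt[k]] else NA_integer_
      if (!is.na(j)) {
        ncod <- j - i + 1L
        has_stop <- TRUE
      } else {
        ncod <- length(codons) - i + 1L
        has_stop <- FALSE
      }
      s0 <- starts[i]
      e0 <- s0 + ncod * 3L - 1L
      out <- rbind(out, data.frame(orf_strand = strand_label, frame = frame,
                                   start = s0, end = e0, has_stop = has_stop,
                                   orf_length_nt = e0 - s0 + 1L,
                                   peptide_length = ncod - as.integer(has_stop)))
    }
  }
  out
}

# longest ORF (nt length and its sequence) for one orientation of a sequence
longest_orf <- function(seq) {
  seq <- toupper(as.character(seq))
  orfs <- orf_scan_one(seq, "+")
  if (!nrow(orfs)) return(list(length_nt = 0L, seq = ""))
  best <- orfs[which.max(orfs$orf_length_nt), ]
  list(length_nt = best$orf_length_nt,
       seq = substring(seq, best$start, best$end))
}
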