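#' Spliced transcript sequences from a genome
#'
#' Concatenates the exon substrings in genomic order. Minus-strand
#' transcripts are reverse-complemented so the result reads 5' to 3'.
#' Strand-unknown (`"*"`) transcripts are returned genome-forward; callers
#' that care about orientation (e.g. coding-potential scoring) must evaluate
#' both orientations, and the returned `DNAStringSet` carries a
#' `both_strands` metadata flag marking them.
#'
#' @param tx transcript `GRangesList`.
#' @param genome a [Biostrings::DNAStringSet] named by chromosome (or a path
#'   to a FASTA file).
#' @return `DNAStringSet` named by transcript id with a logical
#'   `both_strands` metadata column.
#' @export
spliced_sequence <- function(tx, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(unlist(unique(GenomicRanges::seqnames(tx)), use.names = FALSE))
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss)) stop("chromosome absent from genome: ", paste(miss, collapse = ", "))
  strand_chr <- as.character(unlist(unique(GenomicRanges::strand(tx)), use.names = FALSE))
  seqs <- vector("list", length(tx))
  for (i in seq_along(tx)) {
    g <- tx[[i]]
    chr_seq <- genome[[chrom[i]]]
    if (max(end(g)) > length(chr_seq)) {
      stop("exon beyond end of ", chrom[i], " for transcript ", names(tx)[i])
    }
    pieces <- Biostrings::extractAt(chr_seq, IRanges::ranges(g))
    s <- unlist(pieces)
    if (strand_chr[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[[i]] <- s
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(tx)
  S4Vectors::mcols(out)$both_strands <- strand_chr == "*"
  out
}
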