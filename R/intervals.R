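#' Construct a set of transcript models
#'
#' Transcript models are represented as a named [GenomicRanges::GRangesList]
#' of exons, one element per transcript, each sorted by start coordinate with
#' strictly positive intron lengths. Strand is uniform within a transcript;
#' `"*"` encodes an undetermined strand, a first-class state for long-read
#' models that were never assigned to a DNA strand.
#'
#' @param exons a `GRanges` of exons with a metadata column `transcript_id`
#'   (and optionally `gene_id`), or an already-grouped `GRangesList`.
#' @param gene_id optional named character vector mapping transcript id to
#'   gene id; overrides any `gene_id` metadata.
#' @return a `GRangesList` named by transcript id, with `transcript_id` and
#'   `gene_id` metadata columns on the list.
#' @examples
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)),
#'   strand = "+", transcript_id = "t1")
#' tx <- transcript_models(ex)
#' spliced_length(tx)
#' @export
transcript_models <- function(exons, gene_id = NULL) {
  if (is(exons, "GRangesList")) {
    grl <- exons
    if (is.null(names(grl))) stop("GRangesList input must be named by transcript id")
    gid <- S4Vectors::mcols(grl)$gene_id
  } else {
    if (is.null(exons$transcript_id)) stop("exon GRanges needs a 'transcript_id' column")
    tid <- as.character(exons$transcript_id)
    gid_map <- NULL
    if (!is.null(exons$gene_id)) {
      gid_map <- tapply(as.character(exons$gene_id), tid, function(x) x[1])
    }
    keep <- setdiff(colnames(S4Vectors::mcols(exons)), c("transcript_id", "gene_id"))
    S4Vectors::mcols(exons) <- S4Vectors::mcols(exons)[, keep, drop = FALSE]
    grl <- GenomicRanges::split(exons, factor(tid, levels = unique(tid)))
    gid <- if (is.null(gid_map)) NULL else unname(gid_map[names(grl)])
  }
  grl <- endoapply(grl, function(g) sort(g, ignore.strand = TRUE))
  validate_transcripts(grl)
  S4Vectors::mcols(grl)$transcript_id <- names(grl)
  if (!is.null(gene_id)) gid <- unname(gene_id[names(grl)])
  S4Vectors::mcols(grl)$gene_id <-
    if (is.null(gid)) rep(NA_character_, length(grl)) else as.character(gid)
  grl
}

validate_transcripts <- function(grl) {
  if (any(S4Vectors::elementNROWS(grl) == 0)) stop("transcript with no exons")
  chrom_ok <- all(S4Vectors::elementNROWS(unique(GenomicRanges::seqnames(grl))) == 1)
  if (!chrom_ok) stop("all exons of a transcript must lie on one chromosome")
  str_ok <- all(S4Vectors::elementNROWS(unique(GenomicRanges::strand(grl))) == 1)
  if (!str_ok) stop("all exons of a transcript must share one strand")
  multi <- grl[S4Vectors::elementNROWS(grl) > 1]
  if (length(multi)) {
    gap_ok <- vapply(start(multi), function(s) all(diff(s) > 0), logical(1)) &
      vapply(multi, function(g) all(start(g)[-1] - end(g)[-length(g)] > 1), logical(1))
    if (!all(gap_ok)) stop("exons must be disjoint with positive intron length: ",
                           paste(names(multi)[!gap_ok], collapse = ", "))
  }
  invisible(grl)
}

#' Spliced (mature) length of each transcript
#'
#' @param tx a transcript `GRangesList` (see [transcript_models()]).
#' @return integer vector of summed exon widths, named by transcript.
#' @export
spliced_length <- function(tx) {
  setNames(as.integer(sum(GenomicRanges::width(tx))), names(tx))
}

#' Number of exons per transcript
#' @inheritParams spliced_length
#' @return named integer vector; `multi_exon(tx)` is `n_exons(tx) >= 2`.
#' @export
n_exons <- function(tx) setNames(S4Vectors::elementNROWS(tx), names(tx))

#' @rdname n_exons
#' @export
multi_exon <- function(tx) n_exons(tx) >= 2L

#' Intron chains of transcripts
#'
#' @inheritParams spliced_length
#' @return a `GRangesList` of introns (empty elements for single-exon models).
#' @export
introns_of <- function(tx) {
  GenomicRanges::psetdiff(unlist(range(tx), use.names = FALSE), tx)
}

# canonical string key of an intron chain (chromosome + junction coordinates)
intron_chain_key <- function(tx) {
  ic <- introns_of(tx)
  chrom <- as.character(unlist(GenomicRanges::seqnames(range(tx)), use.names = FALSE))
  key <- vapply(seq_along(ic), function(i) {
    g <- ic[[i]]
    if (!length(g)) return(NA_character_)
    paste0(chrom[i], ":", paste(start(g), end(g), sep = "-", collapse = ","))
  }, character(1))
  setNames(key, names(tx))
}

#' Base pairs of overlap between two genomic intervals
#'
#' Symmetric overlap in nucleotides; intervals on different chromosomes (or
#' with an empty intersection) overlap by 0. Strand is ignored.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return integer vector of overlap widths.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' overlap_bp(a, b)  # 50
#' @export
overlap_bp <- function(a, b) {
  if (length(a) == 1 && length(b) > 1) a <- rep(a, length(b))
  if (length(b) == 1 && length(a) > 1) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) == as.character(GenomicRanges::seqnames(b))
  lo <- pmax(start(a), start(b))
  hi <- pmin(end(a), end(b))
  as.integer(ifelse(same, pmax(0L, hi - lo + 1L), 0L))
}

# span (exon hull) of each transcript as an unstranded GRanges
transcript_span <- function(tx, ignore.strand = TRUE) {
  sp <- unlist(range(tx), use.names = FALSE)
  names(sp) <- names(tx)
  if (ignore.strand) GenomicRanges::strand(sp) <- "*"
  sp
}
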