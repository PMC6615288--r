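#' Descriptive statistics of a lincRNA catalog
#'
#' Summarises a transcript set the way a lincRNA catalog is described:
#' transcript and locus totals, spliced-length range and mean, the exon
#' count distribution (fraction with two exons, fraction with fewer than
#' five), and optionally the transcripts falling inside a genomic window
#' together with how many of those exceed ten exons.
#'
#' @param tx transcript `GRangesList`.
#' @param window optional `GRanges` of length 1.
#' @return list `n_transcripts`, `n_loci`, `length_min`, `length_max`,
#'   `length_mean`, `exon_counts` (table), `frac_two_exons`,
#'   `frac_fewer_than_five_exons`, and if `window` given:
#'   `window_transcripts`, `window_over_ten_exons`.
#' @export
annotation_stats <- function(tx, window = NULL) {
  len <- spliced_length(tx)
  nx <- n_exons(tx)
  out <- list(n_transcripts = length(tx),
              n_loci = length(unique(cluster_loci(tx))),
              length_min = min(len), length_max = max(len),
              length_mean = mean(len),
              exon_counts = table(nx),
              frac_two_exons = mean(nx == 2),
              frac_fewer_than_five_exons = mean(nx < 5))
  if (!is.null(window)) {
    span <- transcript_span(tx)
    inside <- IRanges::overlapsAny(span, window, ignore.strand = TRUE)
    out$window_transcripts <- sum(inside)
    out$window_over_ten_exons <- sum(inside & nx > 10)
  }
  out
}
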