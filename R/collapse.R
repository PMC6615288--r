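#' Parameters for redundancy collapse
#'
#' Defaults mirror a ToFU-style intron-chain collapse followed by a
#' CD-HIT-EST-style clustering of single-exon models (`-c 0.95 -aS 0.95`
#' semantics: identity and shorter-sequence coverage thresholds of 0.95).
#' The terminal-end tolerance for intron-chain collapse is not dictated by
#' those tools and is exposed as a parameter (default 100 nt).
#'
#' @param end_tolerance_nt maximum allowed difference between terminal exon
#'   outer ends of merged multi-exon transcripts, in nt.
#' @param identity_frac sequence identity threshold for single-exon merging.
#' @param coverage_frac required overlap as a fraction of the shorter model.
#' @return a list of class `collapse_params`.
#' @export
collapse_params <- function(end_tolerance_nt = 100L, identity_frac = 0.95,
                            coverage_frac = 0.95) {
  stopifnot(end_tolerance_nt >= 0, identity_frac > 0, identity_frac <= 1,
            coverage_frac > 0, coverage_frac <= 1)
  structure(list(end_tolerance_nt = as.integer(end_tolerance_nt),
                 identity_frac = identity_frac, coverage_frac = coverage_frac),
            class = "collapse_params")
}

strands_compatible <- function(a, b) a == "*" | b == "*" | a == b

#' Collapse redundant transcript models
#'
#' Two multi-exon transcripts merge iff they lie on the same chromosome with
#' compatible strands (unknown strand is compatible with either), have
#' identical intron chains, and their terminal exon outer ends differ by at
#' most `params$end_tolerance_nt` at both the 5' and 3' side. Single-exon
#' transcripts merge iff their mutual overlap covers at least
#' `coverage_frac` of the shorter model at `identity_frac` identity (for
#' genome-anchored models the overlapping bases are identical by
#' construction). Merging is transitive; each connected component is
#' represented by its longest member, ties broken by the lexicographically
#' smallest id.
#'
#' @param tx transcript `GRangesList`.
#' @param params a [collapse_params()].
#' @return list of class `collapse_result` with elements `representatives`
#'   (a transcript `GRangesList`, subset of the input) and `membership`
#'   (named character: input id -> representative id).
#' @export
collapse_transcripts <- function(tx, params = collapse_params()) {
  if (!length(tx)) {
    return(structure(list(representatives = tx,
                          membership = setNames(character(0), character(0))),
                     class = "collapse_result"))
  }
  nx <- n_exons(tx)
  chrom <- as.character(unlist(unique(GenomicRanges::seqnames(tx)), use.names = FALSE))
  strand_chr <- as.character(unlist(unique(GenomicRanges::strand(tx)), use.names = FALSE))
  span <- transcript_span(tx)
  edges <- matrix(integer(0), ncol = 2)

  # multi-exon: identical intron chain, ends within tolerance, strands compatible
  multi_idx <- which(nx >= 2L)
  if (length(multi_idx) > 1) {
    key <- intron_chain_key(tx[multi_idx])
    for (grp in split(seq_along(multi_idx), key)) {
      if (length(grp) < 2) next
      gi <- multi_idx[grp]
      for (a in seq_along(gi)[-length(gi)]) {
        for (b in (a + 1):length(gi)) {
          i <- gi[a]; j <- gi[b]
          if (!strands_compatible(strand_chr[i], strand_chr[j])) next
          if (abs(start(span)[i] - start(span)[j]) <= params$end_tolerance_nt &&
              abs(end(span)[i] - end(span)[j]) <= params$end_tolerance_nt) {
            edges <- rbind(edges, c(i, j))
          }
        }
      }
    }
  }

  # single-exon: coverage of the shorter model over the genomic overlap
  mono_idx <- which(nx == 1L)
  if (length(mono_idx) > 1) {
    sp <- span[mono_idx]
    ov <- GenomicRanges::findOverlaps(sp, sp, ignore.strand = TRUE)
    ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
    for (h in seq_along(ov)) {
      i <- mono_idx[S4Vectors::queryHits(ov)[h]]
      j <- mono_idx[S4Vectors::subjectHits(ov)[h]]
      if (!strands_compatible(strand_chr[i], strand_chr[j])) next
      w <- overlap_bp(span[i], span[j])
      shorter <- min(GenomicRanges::width(span)[i], GenomicRanges::width(span)[j])
      if (w >= params$coverage_frac * shorter) edges <- rbind(edges, c(i, j))
    }
  }

  comp <- components_from_edges(length(tx), edges)
  rep_of <- vapply(split(seq_along(tx), comp), function(members) {
    len <- spliced_length(tx[members])
    ids <- names(tx)[members]
    best <- members[len == max(len)]
    best_ids <- names(tx)[best]
    best[order(best_ids)][1]
  }, integer(1))
  membership <- setNames(names(tx)[rep_of[as.character(comp)]], names(tx))
  reps <- tx[sort(unique(unname(rep_of)))]
  structure(list(representatives = reps, membership = membership),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat("collapse_result:", length(x$membership), "inputs ->",
      length(x$representatives), "representatives\n")
  invisible(x)
}

# connected components over n nodes given an edge matrix (2 columns)
components_from_edges <- function(n, edges) {
  if (n == 0) return(integer(0))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}
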