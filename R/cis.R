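#' Protein-coding genes near lincRNA loci (cis-target candidates)
#'
#' For each lincRNA locus, collects every protein-coding gene whose span
#' lies within `window_nt` of the locus span: the span-to-span gap must be
#' at most `window_nt`, inclusive at the boundary, strand-blind. The signed
#' distance is 0 for overlapping/abutting spans (flagged), negative for
#' genes upstream of the locus start and positive downstream of its end.
#'
#' @param linc_loci named `GRanges` of lincRNA locus spans.
#' @param ann an [annotation_set()] (only `protein_coding` genes are used).
#' @param window_nt window size in nt (default 100,000).
#' @return data.frame `locus_id`, `gene_id`, `distance_nt`, `overlapping`.
#' @export
nearby_genes <- function(linc_loci, ann, window_nt = 1e5) {
  genes <- ann$genes[ann$genes$biotype == "protein_coding"]
  out <- data.frame(locus_id = character(0), gene_id = character(0),
                    distance_nt = numeric(0), overlapping = logical(0))
  if (!length(linc_loci) || !length(genes)) return(out)
  if (is.null(names(linc_loci))) names(linc_loci) <- as.character(seq_along(linc_loci))
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(linc_loci),
    IRanges::IRanges(pmax(1L, start(linc_loci) - as.integer(window_nt) - 1L),
                     end(linc_loci) + as.integer(window_nt) + 1L))
  hits <- GenomicRanges::findOverlaps(ext, genes, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  gap <- numeric(length(qi))
  before <- end(genes)[si] < start(linc_loci)[qi]
  after <- start(genes)[si] > end(linc_loci)[qi]
  gap[before] <- -(start(linc_loci)[qi[before]] - end(genes)[si[before]] - 1)
  gap[after] <- start(genes)[si[after]] - end(linc_loci)[qi[after]] - 1
  keep <- abs(gap) <= window_nt
  data.frame(locus_id = names(linc_loci)[qi[keep]],
             gene_id = names(genes)[si[keep]],
             distance_nt = gap[keep],
             overlapping = !before[keep] & !after[keep])
}

#' Functional-term enrichment of a gene set
#'
#' One-sided over-representation test per term: with `N` background genes,
#' `K` of which carry the term, and a selection of `n` genes containing `k`
#' term carriers, the p-value is the hypergeometric upper tail
#' `P(X >= k)` (equivalent to the one-sided Fisher exact test on the 2x2
#' table). The rich factor is `k / K` (term carriers selected over term
#' carriers in the whole gene set). Background genes missing from the term
#' table count as term-less.
#'
#' @param selected character vector of selected genes (subset of
#'   `background`).
#' @param background character vector of background genes.
#' @param term_map data.frame mapping genes to terms: columns `gene_id`,
#'   `term_id` and optionally `term_name`.
#' @param p_cutoff significance cutoff recorded in the `significant` column
#'   (default 0.05).
#' @return data.frame sorted by p-value: `term_id`, `term_name`, `k`, `n`,
#'   `K`, `N`, `p_value`, `rich_factor`, `significant`.
#' @export
enrich_terms <- function(selected, background, term_map, p_cutoff = 0.05) {
  selected <- unique(selected); background <- unique(background)
  if (!all(selected %in% background)) stop("selected genes must be a subset of the background")
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      rich_factor = numeric(0), significant = logical(0))
  if (!length(selected)) return(empty)
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  if (!nrow(tm)) return(empty)
  if (is.null(tm$term_name)) tm$term_name <- tm$term_id
  N <- length(background); n <- length(selected)
  rows <- lapply(split(tm, tm$term_id), function(d) {
    genes_with <- unique(d$gene_id)
    K <- length(genes_with)
    k <- sum(selected %in% genes_with)
    data.frame(term_id = d$term_id[1], term_name = d$term_name[1],
               k = k, n = n, K = K, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               rich_factor = k / K)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$p_value <= p_cutoff
  out
}
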