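suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# build a transcript GRangesList from a list of exon matrices:
# list(t1 = cbind(start, end), ...) with optional chrom/strand vectors
make_tx <- function(exons, chrom = "chr1", strand = "*") {
  chrom <- rep(chrom, length.out = length(exons))
  strand <- rep(strand, length.out = length(exons))
  rows <- do.call(rbind, lapply(seq_along(exons), function(i) {
    m <- exons[[i]]
    data.frame(chrom = chrom[i], start = m[, 1], end = m[, 2],
               strand = strand[i], transcript_id = names(exons)[i])
  }))
  gr <- GRanges(rows$chrom, IRanges(rows$start, rows$end), strand = rows$strand,
                transcript_id = rows$transcript_id)
  transcript_models(gr)
}

random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# single-exon gene annotation from a matrix of (start, end) rows
toy_gene_annotation <- function(gene_pos, biotype = "protein_coding") {
  ex <- lapply(seq_len(nrow(gene_pos)), function(i) cbind(gene_pos[i, 1], gene_pos[i, 2]))
  names(ex) <- rownames(gene_pos)
  tx <- make_tx(ex, chrom = if (is.null(attr(gene_pos, "chrom"))) "chr1"
                else attr(gene_pos, "chrom"))
  annotation_set(tx, setNames(rep(biotype, length.out = nrow(gene_pos)),
                              rownames(gene_pos)))
}

# shared default-condition simulation + pipeline, built once per test run
.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_lincrna_data(synthetic_spec(seed = 20240101))
  }
  .sim_cache$sim
}

default_pipeline <- function() {
  if (is.null(.sim_cache$res)) {
    sim <- default_sim()
    .sim_cache$res <- run_pipeline(
      transcripts = sim$transcripts, genome = sim$genome,
      reference = sim$reference,
      training_coding = sim$mrnas, training_noncoding = sim$training_noncoding,
      training_cds = sim$cds, proteins = sim$proteins, mrnas = sim$mrnas,
      counts_a = data.frame(transcript_id = sim$counts$transcript_id,
                            count = sim$counts$count_a),
      counts_b = data.frame(transcript_id = sim$counts$transcript_id,
                            count = sim$counts$count_b),
      term_map = sim$term_map)
  }
  .sim_cache$res
}
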