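#' Build an annotation set from transcript models
#'
#' An annotation set groups transcript models into gene loci and indexes the
#' gene spans (exon hulls) for interval queries. Gene spans, not CDS hulls,
#' define locus extent: intergenicity is judged against everything a gene
#' transcribes.
#'
#' @param tx transcript `GRangesList` (see [transcript_models()]); its
#'   `gene_id` metadata column assigns transcripts to genes. Transcripts with
#'   a missing gene id become single-transcript genes named after themselves.
#' @param biotype named character vector (by gene id) with values in
#'   `c("protein_coding", "lncRNA", "other_ncRNA")`; unnamed scalar recycles.
#'   Missing genes default to `"protein_coding"`.
#' @return an object of class `annotation_set`: list with elements
#'   `transcripts` (the `GRangesList`), `tx2gene` (named character),
#'   `genes` (a `GRanges` of gene spans, names = gene id, metadata `biotype`).
#' @export
annotation_set <- function(tx, biotype = "protein_coding") {
  gid <- S4Vectors::mcols(tx)$gene_id
  if (is.null(gid)) gid <- rep(NA_character_, length(tx))
  gid <- ifelse(is.na(gid) | gid == "", names(tx), gid)
  span <- transcript_span(tx)
  gsp <- unlist(range(GenomicRanges::split(span, factor(gid, levels = unique(gid)))))
  GenomicRanges::strand(gsp) <- "*"
  bt <- biotype
  if (is.null(names(bt))) bt <- setNames(rep(bt, length.out = length(gsp)), names(gsp))
  btv <- bt[names(gsp)]
  btv[is.na(btv)] <- "protein_coding"
  bad <- setdiff(unique(btv), c("protein_coding", "lncRNA", "other_ncRNA"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  S4Vectors::mcols(gsp)$biotype <- unname(btv)
  structure(list(transcripts = tx, tx2gene = setNames(gid, names(tx)), genes = gsp),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$transcripts), "transcripts in",
      length(x$genes), "genes (",
      paste(names(table(x$genes$biotype)), table(x$genes$biotype), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Subset an annotation set by gene biotype
#' @param ann an `annotation_set`.
#' @param biotypes biotypes to keep.
#' @return an `annotation_set` restricted to those genes.
#' @export
subset_biotype <- function(ann, biotypes) {
  keep_gene <- names(ann$genes)[ann$genes$biotype %in% biotypes]
  keep_tx <- names(ann$tx2gene)[ann$tx2gene %in% keep_gene]
  tx <- ann$transcripts[keep_tx]
  annotation_set(tx, setNames(ann$genes$biotype, names(ann$genes)))
}

#' Genes whose span overlaps a query interval
#'
#' Strand-blind interval query against the indexed gene spans; results equal
#' a brute-force scan over all genes.
#'
#' @param ann an `annotation_set`.
#' @param query a `GRanges` of query intervals.
#' @return list (one element per query) of overlapping gene ids.
#' @export
query_annotation <- function(ann, query) {
  hits <- GenomicRanges::findOverlaps(query, ann$genes, ignore.strand = TRUE)
  out <- rep(list(character(0)), length(query))
  if (length(hits)) {
    sp <- split(names(ann$genes)[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(query)))
    out <- lapply(sp, as.character)
  }
  out
}

#' Read transcript models from a GTF file
#'
#' Exon features are grouped by `transcript_id` into a transcript
#' `GRangesList`. GTF strand `"."` maps to `"*"` (unknown), never silently to
#' `"+"`. A missing `gene_id` attribute is tolerated (left `NA`).
#'
#' @param path GTF file; exon features must carry a `transcript_id` attribute.
#' @return transcript `GRangesList` (see [transcript_models()]).
#' @export
read_transcript_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(transcript_models(GenomicRanges::GRanges(transcript_id = character(0))))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) {
    return(transcript_models(GenomicRanges::GRanges(transcript_id = character(0))))
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("GTF exon features must carry a transcript_id attribute: ", path)
  }
  bad <- which(end(gr) < start(gr))
  if (length(bad)) stop("exon with end < start in ", path)
  ex <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr), IRanges::ranges(gr),
                               strand = GenomicRanges::strand(gr))
  ex$transcript_id <- gr$transcript_id
  ex$gene_id <- if (is.null(gr$gene_id)) NA_character_ else gr$gene_id
  transcript_models(ex)
}

#' Read a reference annotation (with gene biotypes) from a GTF file
#'
#' Biotype is taken from the `gene_biotype` (or `gene_type`) attribute and
#' simplified to `protein_coding` / `lncRNA` / `other_ncRNA`: values
#' containing "lnc" or equal to classic lncRNA labels map to `lncRNA`,
#' `protein_coding` stays, anything else becomes `other_ncRNA`. Absent
#' attributes default to `protein_coding`.
#'
#' @inheritParams read_transcript_gtf
#' @return an [annotation_set()].
#' @export
read_annotation_gtf <- function(path) {
  tx <- read_transcript_gtf(path)
  if (!length(tx)) return(annotation_set(tx))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  raw <- gr$gene_biotype
  if (is.null(raw)) raw <- gr$gene_type
  if (is.null(raw)) raw <- rep("protein_coding", length(gr))
  simp <- simplify_biotype(raw)
  gid <- if (is.null(gr$gene_id)) gr$transcript_id else gr$gene_id
  bt <- tapply(simp, gid, function(x) x[1])
  annotation_set(tx, setNames(as.character(bt), names(bt)))
}

simplify_biotype <- function(x) {
  x <- as.character(x)
  out <- rep("other_ncRNA", length(x))
  out[x == "protein_coding"] <- "protein_coding"
  lnc <- grepl("linc|lnc", x, ignore.case = TRUE) |
    x %in% c("antisense", "processed_transcript", "3prime_overlapping_ncRNA")
  out[lnc] <- "lncRNA"
  out[is.na(x)] <- "protein_coding"
  out
}

#' Write transcript models to GTF
#'
#' Emits one exon feature per exon with `gene_id`/`transcript_id` attributes
#' (GTF 1-based inclusive coordinates; `"*"` strand written as `"."`).
#' `read_transcript_gtf()` of the output reproduces the input models, so
#' read-write-read is a fixed point on canonicalized records.
#'
#' @param tx transcript `GRangesList`.
#' @param path output file.
#' @param extra optional named list of per-transcript character attributes
#'   (e.g. `class_code`, `locus_id`) appended to each exon line.
#' @param source source column label.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(tx, path, extra = NULL, source = "lincforge") {
  gid <- S4Vectors::mcols(tx)$gene_id
  if (is.null(gid)) gid <- rep(NA_character_, length(tx))
  gid <- ifelse(is.na(gid), names(tx), gid)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(tx)) {
    g <- tx[[i]]
    strand_chr <- as.character(GenomicRanges::strand(g)[1])
    if (strand_chr == "*") strand_chr <- "."
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid[i], names(tx)[i])
    if (!is.null(extra)) {
      for (nm in names(extra)) {
        val <- extra[[nm]][i]
        if (!is.na(val)) attrs <- paste0(attrs, sprintf(' %s "%s";', nm, val))
      }
    }
    lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(GenomicRanges::seqnames(g)), source,
                     start(g), end(g), strand_chr, attrs)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_transcript_gtf
#' @param ann an `annotation_set`; its gene biotypes are written as a
#'   `gene_biotype` attribute.
#' @export
write_annotation_gtf <- function(ann, path, source = "lincforge") {
  tx <- ann$transcripts
  bt <- setNames(ann$genes$biotype, names(ann$genes))[ann$tx2gene[names(tx)]]
  S4Vectors::mcols(tx)$gene_id <- unname(ann$tx2gene[names(tx)])
  write_transcript_gtf(tx, path, extra = list(gene_biotype = unname(bt)),
                       source = source)
}

#' Export transcript spans as BED6
#'
#' @param tx transcript `GRangesList`.
#' @param path output file.
#' @param score numeric vector recycled over transcripts.
#' @return `path`, invisibly. Coordinates follow BED convention
#'   (0-based half-open).
#' @export
write_bed <- function(tx, path, score = 0) {
  sp <- transcript_span(tx, ignore.strand = FALSE)
  strand_chr <- as.character(GenomicRanges::strand(sp))
  strand_chr[strand_chr == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(sp)),
                   start = start(sp) - 1L, end = end(sp),
                   name = names(sp),
                   score = rep(score, length.out = length(sp)),
                   strand = strand_chr)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
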