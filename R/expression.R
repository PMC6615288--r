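#' Count primary alignments (or ingest a count table) per transcript
#'
#' Accepts a transcript-space SAM/BAM alignment or a plain two-column count
#' table. Only primary alignments are counted: unmapped, secondary and
#' supplementary records are excluded. References absent from the transcript
#' set are skipped with a warning; transcripts without alignments count 0.
#'
#' @param alignment path to a SAM/BAM file, or a data.frame with columns
#'   `transcript_id` and `count`.
#' @param transcript_ids character vector of transcript ids defining the
#'   counting universe.
#' @return named integer vector of counts over `transcript_ids`. The library
#'   size is their sum.
#' @export
count_reads <- function(alignment, transcript_ids) {
  if (is.character(alignment)) {
    path <- alignment
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
      what = "rname",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE))
    rn <- as.character(Rsamtools::scanBam(path, param = param)[[1]]$rname)
    tab <- table(rn)
    df <- data.frame(transcript_id = names(tab), count = as.integer(tab))
  } else {
    df <- as.data.frame(alignment)
    if (!all(c("transcript_id", "count") %in% names(df))) {
      stop("count table needs columns transcript_id and count")
    }
  }
  unknown <- setdiff(df$transcript_id, transcript_ids)
  if (length(unknown)) {
    warning(length(unknown), " alignment reference(s) not in transcript set; skipped")
    df <- df[df$transcript_id %in% transcript_ids, , drop = FALSE]
  }
  counts <- setNames(integer(length(transcript_ids)), transcript_ids)
  counts[df$transcript_id] <- counts[df$transcript_id] + as.integer(df$count)
  counts
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (library_size * length_nt)`. Linear in `count` at
#' fixed library size and length; invariant under joint scaling of count and
#' library size.
#'
#' @param count mapped reads (>= 0).
#' @param library_size total mapped reads (> 0).
#' @param length_nt transcript spliced length (> 0).
#' @return numeric vector of RPKM values.
#' @export
rpkm <- function(count, library_size, length_nt) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(length_nt <= 0)) stop("length_nt must be > 0")
  count * 1e9 / (library_size * length_nt)
}

#' Per-transcript expression records
#'
#' @param counts named integer vector (see [count_reads()]).
#' @param length_nt named integer vector of spliced lengths covering the
#'   counted transcripts.
#' @param min_support read-count threshold for the `supported` flag
#'   (default 2: at least two mapped short reads).
#' @return data.frame `transcript_id`, `count`, `library_size`, `length_nt`,
#'   `rpkm`, `supported`.
#' @export
expression_records <- function(counts, length_nt, min_support = 2L) {
  lib <- sum(counts)
  if (lib <= 0) stop("library size is 0; cannot compute RPKM")
  len <- length_nt[names(counts)]
  if (anyNA(len)) stop("missing spliced length for some transcripts")
  data.frame(transcript_id = names(counts), count = as.integer(counts),
             library_size = lib, length_nt = as.integer(len),
             rpkm = rpkm(counts, lib, len),
             supported = counts >= min_support, row.names = NULL)
}

#' Welch t-test of group abundance on log2(RPKM + 1)
#'
#' @param group_a,group_b numeric RPKM vectors, each of length >= 2.
#' @return list `statistic`, `p_value`, `exact_separation`. Identical groups
#'   give `t = 0, p = 1`. When both groups have zero variance but different
#'   means the test is degenerate: `exact_separation = TRUE` is flagged and
#'   `p = 0`, `statistic = +/-Inf` reported.
#' @export
group_abundance_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs >= 2 values")
  a <- log2(group_a + 1); b <- log2(group_b + 1)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1, exact_separation = FALSE))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                exact_separation = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       exact_separation = FALSE)
}

#' Two-library differential expression by exact binomial test
#'
#' For each transcript with `count_a + count_b > 0`, the fold change is
#' `((count_a + 0.5)/lib_a) / ((count_b + 0.5)/lib_b)` (0.5 pseudocount) and
#' the p-value comes from the exact binomial test of `count_a` successes in
#' `count_a + count_b` trials with null probability
#' `lib_a / (lib_a + lib_b)`, two-sided by minimum-likelihood summation
#' ([stats::binom.test()]). A transcript is significant iff
#' `max(FC, 1/FC) >= fc_cutoff` and `p <= p_cutoff` (defaults 2 and 0.05; no
#' multiple-testing correction by default, Benjamini-Hochberg optionally).
#' Swapping the two conditions negates `log2_fold_change` and preserves `p`.
#'
#' @param counts_a,counts_b named integer vectors over the same transcripts.
#' @param lib_a,lib_b library sizes (> 0); default to the column sums.
#' @param fc_cutoff,p_cutoff significance thresholds.
#' @param adjust apply Benjamini-Hochberg and test `p_adj <= p_cutoff`
#'   instead of the raw p-value.
#' @return data.frame `transcript_id`, `count_a`, `count_b`, `lib_a`,
#'   `lib_b`, `log2_fold_change`, `p_value` (and `p_adj` if `adjust`),
#'   `significant`.
#' @export
differential_expression <- function(counts_a, counts_b,
                                    lib_a = sum(counts_a), lib_b = sum(counts_b),
                                    fc_cutoff = 2, p_cutoff = 0.05,
                                    adjust = FALSE) {
  stopifnot(lib_a > 0, lib_b > 0)
  ids <- names(counts_a)
  if (is.null(ids) || !identical(ids, names(counts_b))) {
    stop("counts_a and counts_b must be named identically")
  }
  keep <- counts_a + counts_b > 0
  a <- as.integer(counts_a[keep]); b <- as.integer(counts_b[keep])
  p0 <- lib_a / (lib_a + lib_b)
  pval <- vapply(seq_along(a), function(i) {
    binom.test(a[i], a[i] + b[i], p = p0)$p.value
  }, numeric(1))
  fc <- ((a + 0.5) / lib_a) / ((b + 0.5) / lib_b)
  out <- data.frame(transcript_id = ids[keep], count_a = a, count_b = b,
                    lib_a = lib_a, lib_b = lib_b,
                    log2_fold_change = log2(fc), p_value = pval)
  crit_p <- if (adjust) {
    out$p_adj <- p.adjust(pval, method = "BH")
    out$p_adj
  } else pval
  out$significant <- pmax(fc, 1 / fc) >= fc_cutoff & crit_p <= p_cutoff
  out
}
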