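#' Default pipeline parameters
#'
#' Every stage threshold with its standard default: minimum transcript
#' length 200 nt, collapse end tolerance 100 nt and CD-HIT-style 0.95/0.95
#' identity/coverage, coding-probability cutoff 0.44, 100 aa ORF gate with
#' 85% identity over 50 aa protein filter, 95% identity over 50% coverage
#' mRNA filter, structure-match end tolerance 100 nt, minimum 2 exons,
#' 2-read support flag, 100 kb cis window, and DE cutoffs fold change >= 2
#' with p <= 0.05.
#'
#' @return named list of parameters.
#' @export
pipeline_params <- function() {
  list(min_length_nt = 200L,
       collapse = collapse_params(),
       coding = coding_filter_params(),
       structure_end_tolerance_nt = 100L,
       min_exons = 2L,
       min_support = 2L,
       cis_window_nt = 1e5,
       de_fc_cutoff = 2, de_p_cutoff = 0.05)
}

#' Run the lincRNA identification pipeline end to end
#'
#' Executes length gate -> redundancy collapse -> coding filters ->
#' structure classification -> lincRNA selection -> locus clustering ->
#' quantification -> differential expression -> cis-target enrichment, each
#' stage optional where its inputs are optional. Stage input/output counts
#' telescope and every drop is attributed to exactly one reason.
#'
#' @param transcripts transcript `GRangesList` (or GTF path).
#' @param genome `DNAStringSet` (or FASTA path).
#' @param reference [annotation_set()] (or GTF path with biotypes). Genes
#'   with biotype `lncRNA` are used for novelty tiers, all other biotypes
#'   for the structural filters and the intergenicity test.
#' @param coding_model a [train_coding_model()] result, or `NULL` to train
#'   from `training_coding` / `training_noncoding`.
#' @param training_coding,training_noncoding labelled training sequence sets
#'   (used when `coding_model` is `NULL`); the hexamer table is trained on
#'   `training_cds` when given, else on `training_coding`.
#' @param training_cds optional in-frame CDS set for hexamer training.
#' @param proteins optional `AAStringSet` of known proteins.
#' @param mrnas optional `DNAStringSet` of known mRNAs.
#' @param domain_hits optional domain-hit data.frame (or TSV path).
#' @param counts_a,counts_b optional named count vectors (or data.frames
#'   with `transcript_id`/`count`) for the two conditions, indexed by input
#'   transcript id; counts of collapsed members are attributed to their
#'   representative.
#' @param term_map optional gene-to-term data.frame for cis enrichment.
#' @param params see [pipeline_params()].
#' @return list of class `linc_pipeline_result`: `lincRNAs` (transcript
#'   `GRangesList`), `calls` (per-candidate verdict table), `assessment`,
#'   `collapse`, `expression`, `de`, `cis_pairs`, `enrichment`, and `report`
#'   (stage funnel with drop-reason histogram and parameter snapshot).
#' @export
run_pipeline <- function(transcripts, genome, reference,
                         coding_model = NULL,
                         training_coding = NULL, training_noncoding = NULL,
                         training_cds = NULL,
                         proteins = NULL, mrnas = NULL, domain_hits = NULL,
                         counts_a = NULL, counts_b = NULL, term_map = NULL,
                         params = pipeline_params()) {
  if (is.character(transcripts)) transcripts <- read_transcript_gtf(transcripts)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(reference)) reference <- read_annotation_gtf(reference)
  if (is.character(domain_hits)) domain_hits <- read_domain_hits(domain_hits)
  if (!length(transcripts)) stop("no input transcripts")
  stages <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  log_stage <- function(stage, n_in, n_out) {
    stages <<- rbind(stages, data.frame(stage = stage, n_in = n_in, n_out = n_out))
  }

  # 1. length gate (>= 200 nt)
  n0 <- length(transcripts)
  transcripts <- transcripts[spliced_length(transcripts) >= params$min_length_nt]
  log_stage("length_gate", n0, length(transcripts))

  # 2. redundancy collapse
  col <- collapse_transcripts(transcripts, params$collapse)
  tx <- col$representatives
  log_stage("collapse", length(transcripts), length(tx))

  # 3. coding filters
  seqs <- spliced_sequence(tx, genome)
  if (is.null(coding_model)) {
    if (is.null(training_coding) || is.null(training_noncoding)) {
      stop("supply coding_model or training_coding + training_noncoding")
    }
    hex <- if (!is.null(training_cds)) {
      train_hexamer_table(training_cds, training_noncoding)
    } else NULL
    coding_model <- train_coding_model(training_coding, training_noncoding,
                                       hexamer_table = hex)
  }
  assessment <- assess_coding(seqs, coding_model, cutoff = params$coding$cutoff)
  prot_hits <- if (!is.null(proteins)) {
    protein_homology_hits(seqs, proteins, min_orf_aa = params$coding$min_orf_aa)
  } else NULL
  nuc_hits <- if (!is.null(mrnas)) transcript_mrna_hits(seqs, mrnas) else NULL
  filt <- apply_coding_filters(assessment, prot_hits, nuc_hits, domain_hits,
                               params$coding)
  noncoding <- tx[filt$keep]
  log_stage("coding_filters", length(tx), length(noncoding))

  # 4. structure classification and lincRNA selection
  struct_ref <- subset_biotype(reference, c("protein_coding", "other_ncRNA"))
  lnc_ref <- if (any(reference$genes$biotype == "lncRNA")) {
    subset_biotype(reference, "lncRNA")
  } else NULL
  matches <- classify_transcripts(noncoding, struct_ref,
                                  params$structure_end_tolerance_nt)
  calls <- select_lincRNAs(noncoding, matches, struct_ref, lnc_ref,
                           params$structure_end_tolerance_nt)
  lincs <- noncoding[calls$is_lincRNA]
  log_stage("lincRNA_selection", length(noncoding), length(lincs))

  # 5. quantification (counts attributed to representatives)
  expr <- de <- NULL
  lens <- spliced_length(tx)
  agg_counts <- function(cv) {
    cv <- as_count_vector(cv)
    rep_id <- col$membership[names(cv)]
    ok <- !is.na(rep_id)
    tapply(cv[ok], factor(rep_id[ok], levels = names(tx)), sum, default = 0L)
  }
  if (!is.null(counts_a)) {
    ca <- agg_counts(counts_a)
    expr <- expression_records(setNames(as.integer(ca), names(tx)), lens,
                               params$min_support)
    expr$is_lincRNA <- expr$transcript_id %in% names(lincs)
    if (!is.null(counts_b)) {
      cb <- agg_counts(counts_b)
      linc_ids <- names(lincs)
      de <- differential_expression(
        setNames(as.integer(ca[linc_ids]), linc_ids),
        setNames(as.integer(cb[linc_ids]), linc_ids),
        lib_a = sum(ca), lib_b = sum(cb),
        fc_cutoff = params$de_fc_cutoff, p_cutoff = params$de_p_cutoff)
      log_stage("differential_expression", length(lincs), sum(de$significant))
    }
  }

  # 6. cis-target collection and enrichment
  cis_pairs <- enrichment <- NULL
  if (length(lincs)) {
    loci <- locus_spans(lincs, calls$locus_id[calls$is_lincRNA])
    cis_pairs <- nearby_genes(loci, reference, params$cis_window_nt)
    if (!is.null(term_map)) {
      background <- names(reference$genes)[reference$genes$biotype == "protein_coding"]
      enrichment <- enrich_terms(unique(cis_pairs$gene_id), background, term_map)
    }
  }

  drop_hist <- table(c(calls$drop_reason[!is.na(calls$drop_reason)],
                       filt$reason[!is.na(filt$reason)]))
  report <- list(stages = stages, drop_reasons = drop_hist,
                 params = params, n_input = n0, n_lincRNA = length(lincs),
                 n_loci = length(unique(calls$locus_id[calls$is_lincRNA])))
  structure(list(lincRNAs = lincs, calls = calls, assessment = assessment,
                 filter = filt, collapse = col, expression = expr, de = de,
                 cis_pairs = cis_pairs, enrichment = enrichment,
                 report = report),
            class = "linc_pipeline_result")
}

as_count_vector <- function(cv) {
  if (is.data.frame(cv)) {
    setNames(as.integer(cv$count), cv$transcript_id)
  } else {
    stopifnot(!is.null(names(cv)))
    cv
  }
}

# exon-hull span per locus id
locus_spans <- function(tx, locus_ids) {
  span <- transcript_span(tx)
  spl <- split(span, locus_ids)
  out <- unlist(range(spl))
  out
}

#' @export
print.linc_pipeline_result <- function(x, ...) {
  cat("lincRNA identification funnel:\n")
  st <- x$report$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-24s %6d -> %6d\n", st$stage[i], st$n_in[i], st$n_out[i]))
  }
  cat("lincRNAs:", x$report$n_lincRNA, "in", x$report$n_loci, "loci\n")
  invisible(x)
}

#' Evaluate pipeline calls against a simulation's planted truth
#'
#' Collapsed members are resolved through the collapse membership: a truth
#' transcript counts as called when its representative is called a lincRNA.
#' Precision and recall are computed at the truth-transcript level.
#' Differential-expression recall is the fraction of planted fold changes
#' among called lincRNAs that are significant; the null false-positive rate
#' is the significant fraction among called lincRNAs without planted change.
#'
#' @param result a [run_pipeline()] result.
#' @param sim the [simulate_lincrna_data()] simulation it ran on.
#' @return list `linc_precision`, `linc_recall`, `n_called`, and when DE ran
#'   `de_recall`, `de_null_fpr`.
#' @export
evaluate_against_truth <- function(result, sim) {
  truth <- sim$truth
  rep_of <- result$collapse$membership[truth$transcript_id]
  called_reps <- names(result$lincRNAs)
  called <- !is.na(rep_of) & rep_of %in% called_reps
  tp <- sum(called & truth$is_lincRNA_truth)
  out <- list(linc_precision = tp / max(1, sum(called)),
              linc_recall = tp / max(1, sum(truth$is_lincRNA_truth)),
              n_called = sum(called))
  if (!is.null(result$de)) {
    de <- result$de
    truth_by_rep <- tapply(truth$planted_log2FC != 0, rep_of, any)
    planted <- truth_by_rep[de$transcript_id]
    out$de_recall <- if (any(planted)) mean(de$significant[planted]) else NA_real_
    out$de_null_fpr <- if (any(!planted)) mean(de$significant[!planted]) else NA_real_
  }
  out
}
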