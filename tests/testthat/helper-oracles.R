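# Independent brute-force oracles, written against plain base-R data
# structures so they share no code path with the package implementation.

# per-base overlap between two intervals on possibly different chromosomes
oracle_overlap_bp <- function(chr_a, s_a, e_a, chr_b, s_b, e_b) {
  if (chr_a != chr_b) return(0L)
  length(intersect(seq.int(s_a, e_a), seq.int(s_b, e_b)))
}

# every ATG-initiated ORF by walking codons one position at a time
oracle_find_orfs <- function(seq, both_strands = FALSE) {
  scan <- function(s, lab) {
    L <- nchar(s)
    out <- list()
    if (L >= 3) {
      for (i in 1:(L - 2)) {
        if (substr(s, i, i + 2) != "ATG") next
        j <- i
        has_stop <- FALSE
        while (j + 2 <= L) {
          cod <- substr(s, j, j + 2)
          if (cod %in% c("TAA", "TAG", "TGA")) { has_stop <- TRUE; break }
          j <- j + 3
        }
        end <- if (has_stop) j + 2 else i + 3 * ((L - i + 1) %/% 3) - 1
        ncod <- (end - i + 1) %/% 3
        out[[length(out) + 1]] <- data.frame(
          orf_strand = lab, frame = (i - 1) %% 3, start = i, end = end,
          has_stop = has_stop, orf_length_nt = end - i + 1L,
          peptide_length = ncod - as.integer(has_stop))
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  revcomp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  res <- scan(toupper(seq), "+")
  if (both_strands) res <- rbind(res, scan(revcomp(toupper(seq)), "-"))
  if (is.null(res)) return(res)
  res[order(res$orf_strand, res$frame, res$start), , drop = FALSE]
}

# straight-line reimplementation of the TESTCODE lookup-and-weight scheme
oracle_fickett <- function(seq) {
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  pos_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  cont_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  cont_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  cont_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
  b <- strsplit(toupper(seq), "")[[1]]
  b <- b[b %in% c("A", "C", "G", "T")]
  total <- 0
  for (base in c("A", "C", "G", "T")) {
    n1 <- n2 <- n3 <- 0
    for (i in seq_along(b)) {
      if (b[i] != base) next
      p <- (i - 1) %% 3
      if (p == 0) n1 <- n1 + 1 else if (p == 1) n2 <- n2 + 1 else n3 <- n3 + 1
    }
    posv <- max(n1, n2, n3) / (min(n1, n2, n3) + 1)
    contv <- (n1 + n2 + n3) / length(b)
    pi <- 1; while (posv < pos_para[pi]) pi <- pi + 1
    ci <- 1; while (contv < cont_para[ci]) ci <- ci + 1
    total <- total + pos_prob[[base]][pi] * pos_w[[base]] +
      cont_prob[[base]][ci] * cont_w[[base]]
  }
  total
}

# connected components via BFS over an adjacency predicate
oracle_components <- function(n, linked) {
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      for (w in seq_len(n)) if (is.na(comp[w]) && linked(v, w)) queue <- c(queue, w)
    }
  }
  comp
}

# plain-list transcript representation for the classification oracle
as_plain_tx <- function(grl) {
  lapply(seq_along(grl), function(i) {
    g <- grl[[i]]
    list(chrom = as.character(seqnames(g))[1],
         starts = start(g), ends = end(g),
         strand = as.character(strand(g))[1])
  })
}

plain_introns <- function(t) {
  k <- length(t$starts)
  if (k < 2) return(cbind(integer(0), integer(0)))
  cbind(t$ends[-k] + 1L, t$starts[-1] - 1L)
}

plain_exon_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  for (i in seq_along(a$starts)) {
    for (j in seq_along(b$starts)) {
      if (a$starts[i] <= b$ends[j] && b$starts[j] <= a$ends[i]) return(TRUE)
    }
  }
  FALSE
}

# decision-tree classification of one transcript against reference
# transcripts and gene spans, using per-interval set logic only
oracle_classify <- function(t, refs, gene_spans, end_tol = 100) {
  span_t <- c(min(t$starts), max(t$ends))
  hits_gene <- any(vapply(gene_spans, function(g) {
    g$chrom == t$chrom && any(t$starts <= g$end & g$start <= t$ends)
  }, logical(1)))
  if (!hits_gene) return(list(score = 0L, class = "u"))
  it <- plain_introns(t)
  best_s <- 0L; best_cls <- NA_character_; found <- FALSE
  for (r in refs) {
    if (r$chrom != t$chrom) next
    span_r <- c(min(r$starts), max(r$ends))
    if (span_t[1] > span_r[2] || span_r[1] > span_t[2]) next
    ir <- plain_introns(r)
    key_t <- paste(it[, 1], it[, 2]); key_r <- paste(ir[, 1], ir[, 2])
    same_chain <- if (nrow(it) > 0 || nrow(ir) > 0) {
      length(key_t) == length(key_r) && all(key_t == key_r)
    } else plain_exon_overlap(t, r)
    s <- 0L; cls <- NA_character_
    if (same_chain) {
      ends_ok <- abs(span_t[1] - span_r[1]) <= end_tol &&
        abs(span_t[2] - span_r[2]) <= end_tol
      s <- if (ends_ok) 5L else 4L; cls <- "="
    } else if (nrow(it) > 0 && length(key_r) >= length(key_t) &&
               !anyNA(idx <- match(key_t, key_r)) && all(diff(idx) == 1)) {
      s <- 3L
      cls <- if (span_t[1] >= span_r[1] && span_t[2] <= span_r[2]) "c" else "j"
    } else if (any(key_t %in% key_r)) {
      s <- 2L; cls <- "j"
    } else if (plain_exon_overlap(t, r)) {
      s <- 1L
      cls <- if (t$strand != "*" && r$strand != "*" && t$strand != r$strand) "x"
      else if (length(t$starts) == 1 &&
               any(r$starts <= t$starts[1] & t$ends[1] <= r$ends)) "c"
      else "o"
    } else {
      s <- 0L; cls <- "i"
    }
    if (s > best_s || !found) { best_s <- s; best_cls <- cls; found <- TRUE }
  }
  if (!found) return(list(score = 0L, class = "i"))
  list(score = best_s, class = best_cls)
}

# hypergeometric upper tail by explicit enumeration
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(n, K), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}
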