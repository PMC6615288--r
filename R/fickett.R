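# Fickett (1982) TESTCODE lookup tables: for each base, ten probability bins
# indexed by the position parameter (codon-position asymmetry) and by the
# content parameter (base fraction), plus the published per-base weights.
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)

fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1]]
}

#' Fickett TESTCODE statistic
#'
#' The classic alignment-free coding statistic: for each base the position
#' parameter is the maximum of its counts over the three codon positions
#' divided by the minimum plus one, and the content parameter is its overall
#' fraction; each of the eight values is converted to a probability through
#' the published lookup tables and combined with the published weights.
#' Deterministic; invariant under concatenation of identical copies of the
#' sequence (all ratios are preserved).
#'
#' @param seq nucleotide string (character or `DNAString`). Bases other than
#'   `A,C,G,T` (e.g. `N`) are ignored; an effective length below 200 nt
#'   triggers a warning, a sequence with no informative base is an error.
#' @return the TESTCODE score (dimensionless).
#' @export
fickett_testcode <- function(seq) {
  seq <- toupper(as.character(seq))
  bases <- strsplit(seq, "")[[1]]
  keep <- bases %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("sequence contains no A/C/G/T base")
  if (sum(keep) < 200) warning("TESTCODE is calibrated for sequences >= 200 nt")
  pos_in_codon <- ((seq_along(bases) - 1L) %% 3L) + 1L
  score <- 0
  n_tot <- sum(keep)
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(p) sum(bases == b & pos_in_codon == p & keep),
                  numeric(1))
    pos_val <- max(cnt) / (min(cnt) + 1)
    cont_val <- sum(cnt) / n_tot
    score <- score +
      fickett_lookup(pos_val, FICKETT_POSITION_PARA, FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(cont_val, FICKETT_CONTENT_PARA, FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

# score range implied by the tables (used by tests as a sanity bound)
fickett_score_range <- function() {
  lo <- sum(vapply(c("A", "C", "G", "T"), function(b) {
    min(FICKETT_POSITION_PROB[[b]]) * FICKETT_POSITION_WEIGHT[[b]] +
      min(FICKETT_CONTENT_PROB[[b]]) * FICKETT_CONTENT_WEIGHT[[b]]
  }, numeric(1)))
  hi <- sum(vapply(c("A", "C", "G", "T"), function(b) {
    max(FICKETT_POSITION_PROB[[b]]) * FICKETT_POSITION_WEIGHT[[b]] +
      max(FICKETT_CONTENT_PROB[[b]]) * FICKETT_CONTENT_WEIGHT[[b]]
  }, numeric(1)))
  c(lo, hi)
}
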