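---
title: "Identifying multi-exon intergenic lncRNAs from full-length transcript models"
author: "lincforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying multi-exon intergenic lncRNAs from full-length transcript models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Full-length transcript sequencing of a complex tissue produces a large,
highly redundant collection of transcript models. Most are isoforms or
fragments of protein-coding genes; a minority are long noncoding RNAs, and
of those only the *intergenic* ones (lincRNAs) can be called with
confidence when library protocols leave the encoding DNA strand unknown —
antisense and intronic candidates are then hard to distinguish from coding
isoforms. `lincforge` implements the resulting conservative screen: keep
only multi-exon transcripts with no detectable coding potential, no
homology to known proteins or mRNAs, no structural match to annotated
genes, and no overlap with any known protein-coding locus.

This vignette records the models behind each stage, the parameters that
matter, the design choices that were genuinely open, what the synthetic
test bed does and does not emulate, and the limitations we know about.

# Data model

Transcript models are `GRangesList`s of exons (1-based, closed intervals —
the native Bioconductor convention; GTF I/O therefore needs no coordinate
conversion). Strand `"*"` is a first-class "unknown" state that propagates
through the pipeline: collapse treats it as compatible with either strand,
coding scoring evaluates both orientations, and classification never
assigns the antisense class `x` to an unknown-strand model. An
`annotation_set` groups transcripts into genes, indexes gene spans (exon
hulls, not CDS hulls — intergenicity is judged against everything a locus
transcribes) and carries a simplified biotype:
`protein_coding`, `lncRNA`, or `other_ncRNA`.

# Stage models and parameters

## Redundancy collapse

Two multi-exon models merge iff they lie on the same chromosome with
compatible strands, have *identical* intron chains, and their outer ends
differ by at most `end_tolerance_nt` (default 100 nt) on both sides. The
tolerance is the one genuinely free parameter of this stage: collapse
tools do not publish one, and 100 nt is a conservative reading of
"varies only at the 5'/3' end". Fuzzy junction matching was deliberately
not implemented: long-read models that reach this stage are already
splice-corrected, and fuzzy junctions would merge genuine isoforms.

Single-exon models merge when their mutual overlap covers at least
`coverage_frac` (default 0.95) of the shorter model at `identity_frac`
(default 0.95) identity — the `-c 0.95 -aS 0.95` semantics of CD-HIT-EST.
For genome-anchored models the overlapping bases are identical by
construction, so coverage is the operative criterion; the identity
threshold is honoured but trivially satisfied. Merging is transitive
(connected components), and each component is represented by its longest
member, ties broken by the lexicographically smallest id, which makes the
result order-invariant and idempotent.

## Coding potential

Four features feed a logistic model:

* longest ORF length (nt) — ORFs are every ATG-initiated reading frame run
  to the first in-frame stop (or sequence end), with `N`-containing codons
  treated as neither start nor stop;
* ORF coverage — longest ORF over transcript length;
* Fickett TESTCODE — the classic codon-position-asymmetry statistic with
  its published lookup tables and weights. Note that the position
  parameter is `max/(min+1)`, so the score is only asymptotically
  invariant under frame-preserving duplication of a sequence; for short
  sequences the binned lookup can move by one bin.
* hexamer usage bias — the mean log-likelihood ratio of in-frame hexamers
  between coding and noncoding training sets, add-one smoothed. Coding
  training sequences are counted in-frame (step 3), noncoding ones sliding
  (step 1); the asymmetric strides mean the table is non-zero even for
  identical training sets, which is intended — the in-frame reading of a
  CDS *is* the signal.

The logistic weights are not fixed constants: they are trained by
ordinary IRLS logistic regression (`stats::glm`, tolerance 1e-8) on
labelled training transcripts — in the synthetic setting the generator's
reference mRNAs versus background noncoding sequences; in a real analysis
any labelled FASTA pair. On cleanly separable training data glm reports
quasi-separation; predictions remain well defined and the warning is
suppressed. The decision threshold stays at the conventional coding
probability 0.44, applied strictly (`p > 0.44` removes). Strand-unknown
transcripts are scored in both orientations and take the maximum — the
conservative choice, which costs a little specificity (a reverse
orientation can score high by chance) in exchange for never letting an
antisense-of-coding sequence through.

Homology filters mirror BLAST semantics without the BLAST binaries:
Smith–Waterman local alignment via `Biostrings::pairwiseAlignment`
(BLOSUM62, gap 11/1 for peptides; +1/−2, gap 5/2 for nucleotides), with
identity defined as matches over alignment columns. The mRNA screen uses
an explicit seed-and-extend heuristic (exact 24-mers sampled every 12 nt
from the mRNA set select candidate pairs) so the stage stays near-linear
instead of all-pairs quadratic; any pair sharing a ≥ 35 nt exact block is
guaranteed to be seeded, far below the 50 %-coverage threshold that
matters. All thresholds are strict inequalities as worded: > 85 % identity
over > 50 aa for peptides of > 100 aa; > 95 % identity over > 50 % of the
query for the UTR-fragment rule. Domain evidence is ingested as a
precomputed table (one row per hit), not rescanned.

The filters apply in a fixed order and the first failing rule is recorded
(`coding_probability`, `orf_homology`, `orf_domain`, `utr_fragment`), so
drop reasons partition the removed set.

## Structure classification

Against the protein-coding + structural-RNA reference, each transcript
gets a 0–5 match score and a cuffcompare-style class code. Only score 5 —
identical intron chain with both outer ends within 100 nt — has filtering
force; the 0–4 grading (4 identical chain, 3 contiguous subchain, 2 shared
junction, 1 exon overlap, 0 none) is diagnostic only, a deliberate
decision: the published rubric below "perfect match" is undocumented, so
nothing downstream may depend on it. Transcripts sharing any exact intron
with a coding gene are also removed — an isoform-fragment signature.
Class `u` (no exon overlapping any reference gene span, strand-blind)
plus ≥ 2 exons defines a lincRNA.

Two open choices were resolved as follows: intergenicity is tested
span-level and strand-blind (strand is unknown; and "does not overlap a
known gene" is locus-level language), and locus clustering is
single-linkage ≥ 1 bp exon overlap, strand-blind, with deterministic
locus ids ordered by position — the simplest rule consistent with
"putative gene loci". Single-exon transcripts compare as "identical
chain" to single-exon references when they overlap, which makes
`compare_annotations` labels for mono-exon pairs permissive by design.

## Expression and differential expression

RPKM = count × 10⁹ / (library size × length); a transcript is "supported"
at ≥ 2 mapped reads. Counting from transcript-space SAM/BAM keeps primary
alignments only. Group comparisons use Welch's t-test on log₂(RPKM + 1) —
the transform is our choice (none is dictated); zero-variance groups are
reported as an exact-separation special case rather than an error.

The two-library DE screen uses the exact binomial test: condition-A count
as successes out of the pair total, null probability the library-size
ratio, two-sided by minimum-likelihood summation, with a 0.5-pseudocount
fold change and the FC ≥ 2 AND p ≤ 0.05 rule. No multiple-testing
correction by default (the screening convention this reproduces);
Benjamini–Hochberg sits behind `adjust = TRUE`. The test is antisymmetric
under condition swap and calibrated under its own sampling model (see the
calibration test), but see *Limitations*.

## Cis-targets and enrichment

Protein-coding genes whose span lies within 100 kb (span-to-span gap,
inclusive boundary, strand-blind) of a lincRNA locus are cis-target
candidates; signed distances are negative upstream of the locus. Term
enrichment is the one-sided hypergeometric upper tail (equivalently the
one-sided Fisher exact test), with the rich factor *k*/*K*. Only
over-representation is tested. No live web-service queries and no
semantic redundancy collapse of terms — a parent-pruning hook exists in
principle but redundancy handling is out of scope.

# The synthetic test bed

`simulate_lincrna_data()` emulates the statistical structure the screen
relies on, at desk scale (defaults: 2 Mb genome over 4 chromosomes, 60
coding genes, 20 known lncRNAs, 5 structural RNAs, 160 novel transcript
models emitted as 320 end-jittered records, 200,000 reads per condition):

* coding genes carry ATG-initiated CDS of 150–400 codons drawn from a
  deterministic, strongly non-uniform codon-usage table (GC-biased wobble
  position), flanked by UTRs — so ORF length, Fickett and hexamer features
  genuinely separate the classes;
* noncoding sequences are background-composition with every ORF capped
  below 100 codons by rejection sampling, on both strands;
* novel models come in six labelled classes — full coding isoforms,
  3'-UTR fragments, intronic, antisense-like (the only class with a known
  strand), multi-exon intergenic (the planted truth), and mono-exon
  intergenic (planted negatives for the multi-exon rule);
* a third of the planted lincRNAs copy known lncRNA structures and a
  third are altered isoforms at known lncRNA loci, so the novelty tiers
  are exercised; intergenic clearance (≥ 1 kb) is guaranteed against
  protein-coding and structural-RNA genes — the definition the catalog
  uses — not against known lncRNAs;
* every novel model is emitted with an end-jittered duplicate (shrink
  ≤ 80 nt, inside the collapse tolerance) and unknown strand;
* counts are negative binomial (dispersion 0.2, var = μ + 0.2 μ²) around
  planted means, lincRNA means drawn lower than coding means; 10 % of
  transcripts carry a planted 4-fold increase in condition A.

Everything derives from one seed through a single RNG stream; a fixed
seed reproduces the outputs byte for byte.

What the generator does **not** emulate: alignment noise and soft-clips
(models arrive as exact genomic chains), sequencing errors, paralogous
gene families (homology hits have one true source), positional biases in
coverage, and realistic transcriptome-wide abundance (depth and means are
chosen so the DE screen has material to work with; real lincRNA abundances
are far lower). Passing the planted-truth suite therefore demonstrates the
*logic* of the screen, not robustness to noisy alignments or to homology
among near-identical paralogs.

# Numerical and degenerate-input choices

* All interval arithmetic is 1-based closed through IRanges; BED export
  converts to 0-based half-open at the boundary.
* GTF strand "." becomes `"*"`, never silently `+`; missing `gene_id`
  attributes are tolerated (transcripts become their own genes).
* An empty GTF yields an empty annotation, not an error; an alignment with
  zero counted reads is an error at RPKM time (library size must be > 0).
* `hexamer_bias` returns 0 when no valid hexamer exists; Fickett errors on
  sequences with no A/C/G/T and warns below 200 informative nt.
* Collapse, classification and locus ids are deterministic under input
  permutation (canonical sorting, lexicographic tie-breaks).
* Logistic training uses IRLS tolerance 1e-8, max 100 iterations.

Problem sizes in the shipped tests were chosen to keep the full suite and
the acceptance script comfortable on a single CPU (about 5 and 1.5
minutes respectively): 100-sequence ORF-oracle sweeps, 150–200-transcript
classification oracles, 1000-pair interval fuzz, 2000-transcript null
calibrations, and the default simulation above.

# Limitations

* **Two-library DE under overdispersion.** The exact binomial test models
  sampling noise only. When counts are negative binomial with dispersion
  α, the fold-change estimate itself carries irreducible noise:
  sd(log₂ FĈ) = 1.443 · √(2(α + 1/μ)) ≥ 0.91 for α = 0.2 regardless of
  depth. A planted log₂ FC of 2 is then recovered at the |log₂ FĈ| ≥ 1
  rule at best ~86 % of the time, while null transcripts exceed it ~27 %
  of the time — and at realistic counts the binomial p-value does not
  restrain them. No two-library screen can beat this; only replicates and
  a dispersion-aware model (edgeR/DESeq2-class) can. The acceptance script
  reports the realized recall and null false-positive rate under the
  planted conditions so the effect is visible rather than hidden; the
  calibration check shows the same test is well behaved under its own
  Poisson sampling null.
* **Strand-unknown scoring inflates coding false positives.** Taking the
  maximum coding probability over both orientations roughly doubles the
  false-positive rate of the coding call; this is the price of never
  letting reverse-complement coding sequence through, and it biases the
  screen conservative (losing lincRNAs, not admitting coding ones).
* **Score rubric below 5 is package-internal.** Do not compare scores 0–4
  across tools.
* **Single-exon candidates are out of catalog scope** by the multi-exon
  rule, however well supported — mono-exon noncoding transcripts cannot be
  told from unspliced fragments here.
* **Homology screens assume a modest known-mRNA/protein set** (seeded
  pairs then full Smith–Waterman). Against a full mammalian proteome a
  dedicated aligner would be the right tool behind the same interface.
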