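# lincforge

Discovery of multi-exon intergenic long noncoding RNAs (lincRNAs) from
genome-aligned full-length transcript models.

Long-read (e.g. Iso-Seq) transcriptomes yield tens of thousands of
full-length transcript models, most of them redundant isoform variants or
fragments of protein-coding genes. `lincforge` implements the staged screen
that distills such a collection into a lincRNA catalog, for transcriptomics
researchers who have transcript models (GTF + genome FASTA), a reference
gene annotation, and optionally short-read counts:

1. **Redundancy collapse** — multi-exon models merge when they share an
   identical intron chain and their terminal ends differ by ≤ 100 nt;
   single-exon models merge at CD-HIT-EST-style thresholds (identity ≥ 0.95
   over ≥ 0.95 of the shorter model). Merging is transitive; the longest
   member represents each cluster.
2. **Coding-potential filters** — per transcript, the four classic features
   (longest-ORF length *L*ₒ, ORF coverage *L*ₒ/*L*, Fickett TESTCODE score,
   and mean in-frame hexamer log-likelihood ratio) enter a logistic model

   *p* = 1 / (1 + exp(−(b₀ + b₁·*L*ₒ + b₂·*L*ₒ/*L* + b₃·Fickett + b₄·hexamer)))

   trained by ordinary logistic regression on labelled sequences. A
   transcript is removed when *p* > 0.44 (strand-unknown models take the
   maximum over both orientations), when an ORF > 100 aa aligns to a known
   protein at > 85 % identity over > 50 aa (Smith–Waterman, BLOSUM62), when
   a precomputed protein-domain hit exists, or when the transcript aligns
   to a known mRNA at > 95 % identity over > 50 % of its length
   (UTR-fragment rule).
3. **Structure classification** — exon chains are compared to the reference
   annotation: perfect structural matches (score 5 = identical intron chain,
   ends within tolerance) to protein-coding or structural-RNA genes are
   removed, as is any transcript sharing an intron with a coding gene;
   cuffcompare-style class codes (`=`, `c`, `j`, `x`, `i`, `o`, `u`) label
   the rest. Multi-exon class-`u` transcripts — overlapping no known gene
   locus — are the lincRNAs. They are clustered into loci by single-linkage
   exon overlap and tiered by novelty against the known lncRNA annotation.
4. **Quantification and differential expression** — RPKM
   (count × 10⁹ / (library size × length)), a ≥ 2-read support flag, Welch
   t-tests of group abundance on log₂(RPKM + 1), and a two-library screen
   with an exact binomial test (0.5-pseudocount fold change; significant
   when FC ≥ 2 and *p* ≤ 0.05).
5. **Cis-target analysis** — protein-coding genes within 100 kb of each
   lincRNA locus, with hypergeometric (one-sided Fisher) term enrichment
   and rich factors *k*/*K*.

A fully labelled synthetic-data generator (`simulate_lincrna_data()`)
builds a small genome with codon-biased coding genes, known lncRNAs, and
novel transcripts of six planted classes, plus two-condition
negative-binomial counts — giving every stage a planted-truth test bed.

## Worked example

```r
library(lincforge)

sim <- simulate_lincrna_data(synthetic_spec(seed = 1))
res <- run_pipeline(
  transcripts = sim$transcripts, genome = sim$genome, reference = sim$reference,
  training_coding = sim$mrnas, training_noncoding = sim$training_noncoding,
  training_cds = sim$cds, proteins = sim$proteins, mrnas = sim$mrnas,
  counts_a = data.frame(transcript_id = sim$counts$transcript_id, count = sim$counts$count_a),
  counts_b = data.frame(transcript_id = sim$counts$transcript_id, count = sim$counts$count_b),
  term_map = sim$term_map)
res
#> lincRNA identification funnel:
#>   length_gate                 320 ->    315
#>   collapse                    315 ->    135
#>   coding_filters              135 ->     87
#>   lincRNA_selection            87 ->     44
#>   differential_expression      44 ->     14
#> lincRNAs: 44 in 37 loci

table(res$calls$novelty[res$calls$is_lincRNA])
#>              known_structure novel_isoform_of_known_locus
#>                           14                           10
#>                  novel_locus
#>                           20

evaluate_against_truth(res, sim)[c("linc_precision", "linc_recall")]
#> $linc_precision
#> [1] 1
#> $linc_recall
#> [1] 1
```

The funnel reads like a field notebook: 320 input models survive the
200 nt gate (315), collapse to 135 non-redundant transcripts, 87 pass the
coding filters, and 44 multi-exon intergenic transcripts over 37 loci
remain — every planted lincRNA recovered, with no false catalog entries.
The novelty tiers show which calls match known lncRNA structures, which
are new isoforms of known loci, and which come from unannotated loci.
`res$de` holds the two-condition screen for the called lincRNAs, `res$cis_pairs`
and `res$enrichment` the cis-target table.

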