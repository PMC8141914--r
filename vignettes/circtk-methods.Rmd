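---
title: "circtk: detection, annotation and comparison of circular RNAs from chimeric split alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circtk methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circtk)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor is joined to
an upstream acceptor (back-splicing), or when an intron lariat escapes
debranching. A sequencing read that crosses the resulting circular
junction aligns as a *chimeric* read: a splice-aware aligner run in
single-end mode splits it into two segments that map to the same
chromosome and strand but in inverted genomic order. `circtk` starts
exactly there — at the aligner's tabular chimeric-junction output — and
carries the analysis through to a classified circRNA catalog, normalized
expression comparisons across datasets and batches, and cross-species
orthologous circRNA detection. Everything is testable end to end on
synthetic fixtures with planted ground truth, which the package also
generates.

## Detection: circular chimeric reads

A parsed chimeric record holds two segments, each with chromosome,
strand, 1-based reference start and CIGAR. A read is accepted as a
**circular chimeric read (CCR)** iff

1. both segments map to the same chromosome,
2. both map to the same strand,
3. they lie in inverted order — on `+`, the read prefix's reference
   start is strictly downstream of the read suffix's (mirrored on `-`),
4. the smaller segment consumes at least `min_segment = 15` bp of
   reference (computed from the CIGAR: M, D, N, `=`, X operations).

The junction interval follows from segment arithmetic. On `+`:
`junction_end = start1 + refspan(cigar1) - 1`, `junction_start = start2`;
on `-` the mirror. We derive junctions from segment coordinates plus
CIGAR rather than from the file's donor/acceptor breakpoint columns,
whose semantics drift between aligner versions; the breakpoint columns
are retained verbatim for cross-checking. Reads with segments on
different chromosomes or strands are excluded entirely — this is a
circRNA detector, not a fusion caller — and every rejection is tallied
by reason.

CCRs are clustered by **exact** junction identity
`(chrom, strand, start, end)`; no fuzz window is applied, which keeps
circRNA identity well-defined for catalog intersections and orthology.
Each read counts once; two single-end mates of one fragment may
legitimately support the same junction twice.

## Filters

* **Support**: clusters with fewer than `min_ccr = 5` CCRs are dropped as
  rare circularization events that cannot be distinguished from artifacts.
* **Size**: candidates with genomic size `< read_length / 2 + 5` are too
  small relative to the reads supporting them for the split alignment to
  be trustworthy; at 100 bp reads the smallest annotatable size is 55 bp.
  These candidates are *kept* in the catalog (class `size_excluded`) but
  never sent to the classifier.
* **Intersection** (for external catalogs from two standard detection
  tools): only junctions present in both lists are kept, and a junction
  must carry at least `min_bsj = 4` supporting reads, applied *after*
  the intersection. List A is treated as the quantification list, so the
  intersected record keeps A's count. Strand-unaware external records
  (strand `"."`) match either strand and are logged as lenient matches.

## Annotation

Against an Ensembl-style annotation (GTF or GFF3, auto-detected), with
introns derived per transcript between adjacent exons:

* **exonic** — both junctions coincide exactly with exon boundaries of
  the same gene on the candidate's strand (the two exons may be one).
* **sub-exonic** — both junctions fall *strictly* inside a single exon;
  sense or antisense to the host gene. Exons of rRNA genes are excluded:
  back-splice-like reads on rRNA are overwhelmingly depletion artifacts.
* **intronic** — the candidate lies within one intron of its own strand,
  its 5' junction sits exactly on the intron donor, and its 3' junction
  is at most `acceptor_tolerance = 60` bp inside the intron from the
  acceptor — the signature of a lariat-derived circle trimmed back from
  the branch point.
* **unannotated** — everything else, including candidates whose two
  boundaries match exons of *different* genes; these are flagged
  `multi_gene` rather than given a fusion class, since such events are
  exceptional and not a recurrent biological category.

Where several classes match, the primary class follows the precedence
**exonic > intronic > sub-exonic (sense) > sub-exonic (antisense) >
unannotated**. Exonic is the only class with exact evidence at both
junctions, which is why it outranks the donor-anchored intronic class
and the containment-only sub-exonic class. This precedence is a design
choice the annotation format keeps auditable: all alternative matches
are preserved in `all_matches`. Two related choices were genuinely open
and are resolved as follows: exonic matching requires the two exons to
belong to the same *gene* (not the same transcript), the weakest
constraint consistent with a single parent gene; and a junction that
merely touches an exon boundary on one side is not sub-exonic (strict
containment is read literally).

Introns are transcript-level: a splice donor/acceptor is a property of
a transcript, so identical introns from several transcripts are
deduplicated by coordinates while all (gene, transcript) attributions
are retained.

All internal coordinates are 1-based fully-closed, as in GTF; the single
conversion to BED's 0-based half-open convention happens in
`write_bed()`, avoiding off-by-one drift.

The cluster scan for unannotated circRNAs (`find_unannotated_clusters`)
merges unannotated junction intervals whose gaps are below `window` and
reports clusters of at least `min_count` members with their share of all
unannotated circRNAs. Such clusters flag genome regions with assembly or
annotation problems (collapsed repeats, missing gene models) rather than
novel loci. Defaults — window 10 kb, minimum 10 members — are chosen to
capture the 20–300 kb problem regions seen in practice without merging
chromosome arms.

## Quantification and comparison

Counts are junction reads per circRNA per dataset. Normalization is
two-layered, as is standard for between-library count comparisons:
per-million scaling by the dataset's uniquely mapped reads, and TMM
(trimmed mean of M-values) factors computed by edgeR with the published
trims (0.30 on M, 0.05 on A). Batch-level expression is the **mean** of
the normalized values over the batch's datasets; sum and mean are
rank-equivalent within a batch, and the mean stays comparable across
batches of different sizes. Parent-gene expression is the sum over the
gene's circRNAs, with the mass of parentless circRNAs reported
separately so column totals are conserved.

Top-N rankings (`top_n`, default 100) break ties lexicographically for
reproducibility, and `overlap_pct` compares two rankings as plain sets.
Cross-species (or cross-tissue) expression correlations are Pearson on
log10 values after discarding pairs below `log10(value) > 1.2` on either
side — weakly expressed circRNAs carry mostly counting noise; Spearman
is available by flag. Group comparisons of per-dataset summaries use a
two-sided exact rank-sum test; with ties and at most 10 values per group
the exact p-value is obtained by midrank enumeration over all group
assignments, since the standard implementation falls back to a normal
approximation there.

## Orthologous circRNAs

Each circRNA is represented by the 200 nt sequence crossing its circular
junction (100 nt on each side, in transcript orientation; the `-` strand
construction is the reverse complement of the `+` one). Circles smaller
than the flank wrap around the circle — the junction-crossing sequence
is a property of the circular transcript, which simply reads around the
circle again — rather than being truncated.

Sequences of two species are aligned all-against-all with local
(Smith–Waterman) alignments under megablast-like scoring (match +2,
mismatch −3, gap open 5, extend 2) and a minimum reported score of 80.
These values are conventional rather than tuned: random unrelated
200-mers score around 20–40 under this scheme while 10%-diverged
homologs score above 250, so the floor separates the two regimes by a
wide margin, and the reciprocal-best-hit criterion — not the raw score —
carries the decision. **Reciprocal best hits** with unambiguous (untied)
best hits on both sides are reported as orthologous circRNA pairs; ties
invalidate the pair rather than being resolved arbitrarily.
Concordance with gene-level one-to-one orthologs is assessed separately
(`gene_concordance`), counting pairs whose parent genes appear in the
supplied ortholog table.

## The synthetic-data generator

`sim_spec()` fixes the study conditions: a 100 kb chromosome carrying
multi-exon protein-coding genes on both strands, a multi-exon lncRNA, a
mono-exonic ribozyme-like small non-coding gene, an rRNA gene and ample
intergenic space; 100 bp reads (the dominant 2×100 sequencing design);
segment spans of 20–80 bp; ~30 planted circRNAs covering every class
(including an rRNA-hosted circle that must end up unannotated and a
two-gene boundary case); and decoy reads — ordinary linear-splice
chimeras, trans-chromosome chimeras, opposite-strand pairs and
undersized segments — that a correct detector must reject. Exon lengths
(150–400 bp) and intron lengths (300–800 bp) are at the compact end of
mammalian annotation so fixtures stay small. A single seed drives every
draw, so fixtures are bit-reproducible; chimeric records are synthesized
directly at the junction-table level, never via read simulation plus an
external aligner, because the package's contract starts at that table.

The diverged ortholog genome applies i.i.d. substitutions (no indels) at
a configurable rate, default 5% — roughly the neutral divergence of the
closely related ruminant pair this workflow targets. Count matrices are
negative binomial (size 10) around the planted support scaled by
per-dataset depth factors.

What the generator does *not* emulate: sequencing errors and quality
scores, alignment ambiguity in repeats, overlapping genes, indel
divergence, GC or length biases, and fragment-level dependence between
mates. Passing the planted-truth suites therefore demonstrates that the
*logic* of detection, classification, normalization and orthology is
exact under clean conditions; it does not certify recall on real
alignments, where the aligner's chimeric-calling behavior dominates.

## Numerical and degenerate-input choices

* Junction derivation rejects records whose derived start is not
  strictly below the end (tallied `inconsistent_junction`).
* `top_n` excludes zero-expression entries; shorter lists are messaged.
* An all-zero count column is an error in TMM (factor undefined), named
  by column.
* Correlation with fewer than three surviving pairs is an error, not a
  number.
* Dominance of a single-isoform gene is reported as `Inf`, and gene
  concordance of an empty pair list as `NaN`, keeping arithmetic honest.
* The rank-sum enumeration compares `|W - E(W)|` with a 1e-9 slack so
  midrank ties at the observed statistic count as at-least-as-extreme.

## Problem sizes used in the test suite

The shipped suites run on one 100 kb chromosome, ~30 planted circRNAs,
count matrices of 200 features × 4 datasets, and ortholog panels of 50
true pairs plus 100 decoys per species at 5% divergence — sizes at which
every oracle (brute-force interval scan, dictionary clustering,
sort-then-sweep, exact rank-sum enumeration, independent TMM
reimplementation) is exact and fast. These were chosen as the smallest
configurations that exercise every rule boundary (15 bp segments, 5-CCR
support, 55 bp size cutoff at 100 bp reads, 60 bp acceptor tolerance,
BSJ ≥ 4 intersection) with margin on both sides.

## Limitations

Identity is the junction: distinct internal structures sharing a
junction are indistinguishable here, and no internal-structure inference
is attempted. The detector consumes one chimeric dialect (the classic
14-column single-end table, trailing columns tolerated). Orthology is
two-species reciprocal best hits; no synteny, no N-way graphs. Multiple
testing across many batch comparisons is deliberately not corrected —
p-values are reported raw and should be treated as descriptive.
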