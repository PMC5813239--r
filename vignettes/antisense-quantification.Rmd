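---
title: "Quantifying sense and anti-sense transcription from stranded RNA-seq"
author: "antisenseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sense and anti-sense transcription from stranded RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A stranded paired-end RNA-seq library preserves which genomic strand each
fragment was transcribed from. Most fragments over an annotated gene align on
the gene's own strand, but a measurable minority align *opposite* to it while
still matching the gene's exon structure — they avoid introns and cross
exon/exon junctions in reverse orientation. This exonic anti-sense signal is
biologically distinct from the ENSEMBL "antisense" *biotype* (genes that live
in introns of a host gene on the opposite strand), and in degenerating retinal
tissue it separates disease from normal samples more cleanly than sense
expression does. `antisenseq` quantifies both signals per gene and carries
them through sample QC, depth normalization, clustering, differential
expression and cis co-localization.

## The quantification model

A **fragment** is a read pair pooled into one unit: the union of both mates'
aligned blocks (N-gapped CIGAR segments), the set of observed splice
junctions, and a transcription strand inferred from FLAG bits under the
declared protocol. Under the dUTP ("firststrand") chemistry read 2 carries
the transcript strand; under "secondstrand" read 1 does; an unstranded
library yields no strand and such fragments cannot be channelled.

A fragment is **consistent with a splice form** (transcript) when

1. every aligned block lies inside the transcript's exons,
2. every observed junction is an annotated junction of that transcript, and
3. no annotated junction internal to the fragment's genomic span is missing
   from the fragment (no exon-skipping mismatch).

The strand is deliberately not part of this test. Candidate genes are then
split by strand: genes with a consistent splice form on the fragment's
transcription strand are *sense* candidates, genes with a consistent splice
form on the opposite strand are *anti-sense* candidates. Exactly one sense
candidate wins the sense channel; sense takes precedence over anti-sense, so
ordinary transcription of a gene can never inflate the anti-sense count of an
overlapping opposite-strand neighbour. A fragment with no sense candidate and
exactly one anti-sense candidate is counted anti-sense. Multiple candidates
in the winning channel make the fragment ambiguous; ambiguous fragments are
counted for no gene, and sense + antisense + ambiguous + unassigned equals
the fragment total exactly, per sample.

Rule 3 deserves a caveat. The span between two mates is unsequenced; a
junction falling in that inner gap cannot be observed, and the strict rule
therefore treats such fragments as inconsistent with that splice form. With
the default fragment geometry (180 +/- 25 bp fragments, 100 bp reads) inner
gaps are rare and short, so the loss is a percent-scale thinning that is
uniform across a gene's fragments. `strict_span = FALSE` relaxes rule 3 to
observed junctions only; the default keeps the strictest reading. A still
looser `mode = "overlap"` (any exon-union overlap) exists for sensitivity
analysis only.

Counting operates on fragments, not reads: both mates report on one cDNA
molecule, and counting them separately would double-weight covered genes
without adding information.

### Average coverage and expression calls

Per gene and sample, **normalized average coverage** is the number of aligned
fragment bases falling inside the gene's exon union divided by the union
length (bp), computed after depth normalization, with no further scaling.
A gene is called expressed at coverage >= 1 (inclusive). Three tables leave
the quantifier: gene-sense, gene-anti-sense, and ncRNA (the sense table
restricted to non-coding biotypes).

## Annotation handling

The GTF (ENSEMBL dialect) must carry gene/transcript/exon features with
`gene_id`, `transcript_id` and `gene_biotype`. Internally every interval is
0-based half-open; conversion happens only at the GTF/SAM boundary, which
keeps interval arithmetic uniform. Genes whose biotype contains the substring
`pseudogene` are removed before any counting — their many near-identical
copies make alignments unreliable — and the substring match covers the
processed/unprocessed/transcribed variants. The non-coding universe defaults
to every retained biotype except `protein_coding`; the ENSEMBL "antisense"
biotype is *included* in that universe and also reported as its own biotype
row, and can be excluded via the `exclude` argument where a narrower
definition is wanted. Genes on contigs absent from the declared genome
layout are dropped with a warning.

## Read-level normalization

Depth is equalized *before* quantification: each retained sample is
subsampled, fragment-wise and without replacement, to the minimum fragment
depth across samples, under a seed derived from the master seed and the
sample's position in the plan. The realized depth is exact, mates are never
split, and record order (hence coordinate sorting) is preserved. This is a
deliberate, declared mechanism for read-level normalization — deterministic,
testable, and sufficient to make "average coverage" comparable across
samples; it does not attempt to reproduce any particular external pipeline's
resampling internals, and it deliberately avoids model-based scalings
(TPM/TMM) whose assumptions the anti-sense channel violates.

## Sample QC

Four per-sample metrics, in a fixed precedence (the first violated rule is
the recorded reason): mapped fraction of records (floor 0.93, the
study-grade mapping rate for retained libraries); fragments overlapping
rRNA-biotype genes over total (ceiling 0.35); fragments on the mitochondrial
contig over total (ceiling 0.20); and a cross-tissue contamination score —
fragments in the *other* tissue's marker genes over gene-assigned fragments
(ceiling 0.10). The three contamination ceilings are explicit stand-ins for
qualitative failure descriptions; they are configurable and are written into
every QC report header. The score is a ratio of assigned fragments rather
than an absolute count so that it is invariant to sequencing depth.

## Statistics

**Variability ranking.** The coefficient of variation of average coverage
across all samples uses the sample (n-1) standard deviation; zero-mean genes
are excluded, ties break lexicographically by gene id, and the default
selection keeps the top 1000.

**Clustering.** Each signal-class matrix is column-normalized to a
probability distribution and samples are compared by Jensen-Shannon
divergence in log base 2 — symmetric, bounded by 1, and insensitive to the
remaining depth differences. Hierarchical clustering uses average linkage by
default; flat cuts are scored by cluster purity against the sample sheet.
Clustering runs on all genes with nonzero signal by default; clustering on
the top-variable subset is available by passing `top_variable()` output,
since the right choice depends on how concentrated the signal is.

**Differential expression.** Two-group contrasts (disease vs normal within
tissue) are fitted per signal class with limma's voom/lmFit/eBayes chain:
log2-CPM with a 0.5 offset, a lowess mean-variance trend (span 0.5) giving
inverse-variance observation weights, per-gene weighted least squares, and
empirical-Bayes shrinkage of residual variances (moderated t); with fewer
than 10 genes no trend can be fitted and the fit falls back to the
pooled-prior moderated t with uniform weights. Benjamini-Hochberg q-values
come from `p.adjust`. One choice matters and is easy to miss: after
read-level normalization every sample has the same total depth, so the
**library size passed to voom is that common depth**, not the column sums of
the channel matrix. Anti-sense activation is strongly asymmetric (many genes
up, few down); normalizing by the anti-sense column sums would shrink every
null gene in the activated condition and manufacture false "down" calls,
whereas the fixed library size keeps the channel on an absolute scale. The
per-tissue significance presets follow the study design the package targets:
anti-sense q <= 1e-4 (PR) and 1e-3 (PRCS); sense and ncRNA q <= 0.05 (PR)
and 0.25 (PRCS).

**Co-localization.** Protein-coding regulatory domains follow the GREAT
"basal plus extension" rule, re-implemented locally (no web service): basal
= 5 kb upstream / 1 kb downstream of the TSS, strand-aware; extension to the
nearest flanking basal domain, capped at 1 Mb from the TSS and clipped to
chromosome bounds. A non-coding gene is represented by its locus midpoint
(configurable to TSS; the midpoint is the less arbitrary choice for the
mostly short, single-exon loci involved) and assigned to every domain
containing it. Ontology enrichment is intentionally out of scope — the
output is the gene mapping a pathway tool consumes.

## The simulator

The simulator is the package's complete test surface, and its defaults *are*
the study conditions: two tissues (PR, PRCS) x two states (normal, AMD),
five replicates per cell by default (the scripts under `analysis/` use eight
per cell, i.e. 32 libraries, with six planted QC failures: one rRNA-heavy,
three chrM-heavy, two cross-tissue), 100 bp paired ends from 180 +/- 25 bp
fragments under the firststrand protocol. It emits a small four-contig
genome (including a chrM-like contig and an rDNA locus), single- and
multi-exon genes (2-6 exons, up to two splice forms) across the profiled
biotypes — with "antisense"-biotype genes placed inside introns of
protein-coding hosts on the opposite strand — and coordinate-sorted SAM
alignments with proper FLAG/CIGAR/TLEN fields. Anti-sense fragments are
sampled from reversed-strand copies of annotated splice forms, so they are
exonic and junction-respecting by construction. Per-gene counts are Poisson
around rate x library size (negative binomial via the `overdispersion`
option); sense rates are log-normal with tissue markers boosted 8x in their
own tissue; a configurable subset of genes carries constitutive anti-sense
at 5% of its sense rate; disease samples additionally activate
tissue-specific gene sets (anti-sense from zero) or multiply baseline
anti-sense 4x. Contamination draws fragments from rRNA genes, chrM genes,
and the other tissue's markers at configured fractions. Every planted count
is recorded in a truth table, and each read name encodes its source sample,
gene, channel and class, which is what the recovery tests compare against.

What the simulator does **not** emulate: sequence content and sequencing
error (bases are constant; the pipeline reads only coordinates, FLAGs and
CIGARs), mapping ambiguity and multimapping, GC/length bias, isoform-switch
expression (transcripts of a gene are sampled uniformly), unannotated
transcription, and the scale and structural messiness of a real annotation.
Passing tests therefore demonstrate that the *computation* is correct under
its stated assumptions — not that those assumptions absorb every artifact of
real libraries, where alignment quality and annotation completeness dominate.

## Numerical and degenerate-input choices

JSD uses the 0 log 0 = 0 convention and errors on zero-sum sample columns
(an all-zero channel is a data problem, not a distance of zero). BH
q-values, CV ties and gene ordering are deterministic. Subsampling seeds
derive from the master seed by a fixed linear map, keeping every derived
seed a valid 32-bit integer and every stage independently reproducible.
Orphaned SAM records are dropped with a warning before subsampling so the
fragment count stays exact. Single-exon genes have empty junction sets and
participate in rules 1-3 trivially. Fragments on contigs unknown to the
annotation are routed to `unassigned` and logged.

## Problem sizes

The shipped tests and the acceptance script exercise: the assigner against a
base-level brute-force oracle on 30 genes x 5,000 fragments; truth recovery
on 50,000 fragments per sample (Spearman per channel); the full 32-sample
study at 8,000 fragments per sample for QC, normalization, clustering and
DE; and count-level DE calibration at 2,000 genes, 5 vs 5 (null and planted
4x folds). These sizes were chosen so the complete battery runs comfortably
on a laptop-class single core while leaving each statistical check enough
resolution to fail visibly if the implementation drifts.

## Known limitations

Only two-group contrasts without covariates are supported; batch or donor
effects need an external design. Ambiguous fragments are discarded rather
than fractionally allocated (conservative, and rare outside dense overlapping
loci). The anti-sense channel requires full structural compatibility, so
anti-sense transcription that extends into introns is invisible by design.
Isoform-level quantification, annotation-free anti-sense assembly, and
enrichment statistics are out of scope.
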