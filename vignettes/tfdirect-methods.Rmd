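---
title: "Methods: calling direct transcription-factor targets with tfdirect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling direct transcription-factor targets with tfdirect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfdirect)
```

## The problem

An ETS-family transcription factor such as FLI1, amplified in a subset of
germinal-center B-cell (GCB) diffuse large B-cell lymphomas, binds
thousands of genomic sites, and silencing it perturbs a large part of the
transcriptome. Most perturbed genes are downstream ripples. The direct
target network — genes the factor binds *and* regulates — is what links
the factor to phenotype, and it is inferred by intersecting independent
evidence layers: ChIP-Seq binding, knockdown differential expression,
correlation with the factor across clinical specimens, and overlap with
CRISPR-defined essential genes. `tfdirect` implements that intersection as
a tested, reusable pipeline.

## Coordinate frame and peak annotation

All user-facing coordinates are 0-based half-open (BED convention); GTF
input is converted at the reader boundary and nowhere else. A gene's TSS
is its 5' end on its own strand: `start` for `+`, the last covered base
for `-`. Multi-transcript genes collapse to one TSS per `gene_id` — the
analysis is gene-level throughout, which is the unit at which targets are
reported.

The promoter is the symmetric window `[tss - flank, tss + flank)` with
`flank = 3000` bp by default, clipped at the contig origin. Strand only
decides which end is the TSS; the window itself is symmetric, the minimal
reading of a "within 3 kb of the TSS" rule.

Peak context uses the precedence **promoter > intragenic > intergenic**
with a ≥ 1 bp overlap rule (no fractional-overlap threshold; there is no
principled fraction to prefer, and the rule is configurable at the overlap
layer). A promoter peak is credited to *every* gene whose window it
overlaps, not only the nearest — promoters of divergent gene pairs
overlap, and a single peak can sit in both. The signed TSS distance is
measured from the peak midpoint, positive downstream of the TSS. Peaks on
chromosomes absent from the annotation are classified intergenic with a
warning rather than dropped, so peak counts always reconcile.

Interval queries are served by GenomicRanges/IRanges indexes; the test
suite verifies every context call, promoter assignment and nearest-TSS
distance against exhaustive double-loop scans, so the indexes are an
implementation detail, not an assumption.

## Distal (enhancer-linked) binding

Peaks farther than `flank` from every TSS cannot be assigned by proximity.
They are routed through an enhancer–promoter interaction map (BEDPE-like,
as produced by Capture Hi-C experiments in lymphoblastoid cells): an
eligible peak overlapping an enhancer anchor contributes all genes
annotated to the interacting promoter anchor. Genes that *also* carry a
promoter peak are excluded from the distal-only set, so promoter and
distal evidence never double-count a gene; this mutual exclusion is
asserted at integration time. If a file's gene labels sit on the first
anchor, the pair is flipped — whichever anchor carries labels is the
promoter side. No interaction-score threshold is applied by default
(public maps ship pre-thresholded; a minimum-score option exists). Peaks
on chromosomes with no annotated TSS have no defined TSS distance and are
treated as distal-eligible.

## Differential expression

Counts are filtered to genes with CPM > 1 (strict) in at least 3 samples,
then transformed to `log2(CPM + 0.5)`. The moderated t-test fits, per
gene, OLS of log-expression on condition plus a cell-line blocking factor
— the two cell lines are analyzed jointly, one list, with between-line
baseline differences absorbed by the block. The gene-wise residual
variances `s2_g` on `d` df are shrunk toward a prior `(d0, s0_sq)`
estimated in closed form by matching the first two moments of `log(s2_g)`
to a scaled inverse-chi-square model (digamma/trigamma inversion, the
standard empirical-Bayes estimator). The posterior variance
`(d0*s0_sq + d*s2_g)/(d0 + d)` yields a t statistic on `d0 + d` df.

Two properties pin the implementation down and are tested numerically:
with `prior_df = 0` it reproduces the ordinary OLS t exactly, and with
`prior_df = Inf` every gene's posterior variance collapses to the pooled
prior. The default estimated fit also agrees with limma's `eBayes` on the
same design, as an independent cross-check.

The voom precision-weight scheme is deliberately **not** reproduced:
log2-CPM with constant-variance empirical-Bayes moderation (the
"limma-trend" style) preserves the statistical intent — moderated t, BH
adjustment, the stated thresholds — without the weight machinery, and is
well calibrated on the count depths simulated here (the all-null type-I
rate at p < 0.05 lands near 0.05 in the acceptance checks).

Calls use |log2FC| > 0.1 and BH-adjusted p < 0.05, both strict: a gene at
exactly the threshold is not called. The sign convention is fixed once:
log2FC is knockdown minus control, so a **negative** log2FC after
knockdown means the factor **positively** regulates the gene.

## Clinical support and subtype contingency

Across clinical specimens, each gene's Pearson correlation with the
factor is tested via `t = r*sqrt((n-2)/(1-r^2))` on `n - 2` df; genes with
p < 0.01 (strict) are retained with their sign. A target has *clinical
support* when it is significant **and** sign-concordant with its
regulation (positively regulated targets should correlate positively with
the factor); concordance can be disabled, but the default requires it —
the evidence claim is "correlated in the direction the regulation
predicts", not merely "correlated". The screen can be restricted to a
subtype (e.g. GCB specimens only) via a filter.

Median dichotomization splits specimens into high (`> median`) and low
(`<= median`; ties deterministically to low) factor expressors; the 2×2
table against GCB/ABC subtype is tested with the two-sided Fisher exact
test — exact at all counts, which a chi-square is not — and the odds ratio
uses the Haldane 0.5 correction when a cell is empty.

## Integration and tiers

A gene is a **direct target** iff it is bound (promoter union, or
distal-only) and its DE call is not `ns`. Evidence accumulates into a tier
(1 = binding + DE, +1 for clinical support, +1 for essentiality) while
clinical support and essentiality are also kept as independent flags —
essentiality does not presuppose clinical support. The run summary reports
raw intersection counts per regulation sign, each recomputed from the
per-gene table so set identities always hold. Genes present in the DE
table but absent from the annotation simply carry `binding = none`; the
annotated-peak TSVs retain everything needed to reconcile the namespaces.

## Motif and gene-set readouts

The PWM layer scores every window on both strands with `log2(p/bg)`
(pseudocount 0.25 per column, uniform background by default); the default
hit threshold is 80% of the PWM's maximum achievable score, a common
operating point for core-motif scans. Windows containing `N` are skipped.
Enrichment compares the fraction of peak sequences with ≥ 1 hit to a
size-matched background — by default a per-sequence **dinucleotide
shuffle** (Altschul–Erikson Eulerian-walk shuffle, preserving mono- and
dinucleotide counts exactly, verified per sequence in tests) — with a
two-sided Fisher exact test. The bundled ETS-core matrix
(`inst/extdata/ets_core.jaspar`, consensus `ACAGGAAGTG`) is a synthetic
stand-in for a database motif; any JASPAR-format matrix can be supplied.
De novo motif discovery is out of scope: scan-based enrichment against a
composition-preserving background answers the same question — are bound
regions enriched for the factor's consensus — in a directly testable form.

Over-representation uses the upper-tail hypergeometric `P(X >= k)` with BH
across the collection. The universe is the **expressed** universe (genes
passing the CPM filter), standard ORA practice: promoter-bound unexpressed
genes cannot be called targets, so including them would inflate
enrichment.

## The synthetic-data generator

The generator emulates the study design the pipeline is built for: two
GCB-derived cell lines with three knockdown and three control RNA-Seq
replicates each; ChIP peaks planted in the promoters of true promoter
targets and in enhancer anchors interaction-linked to true distal targets;
indirect genes with expression effects but no binding; background peaks in
intragenic and intergenic space; a 150-specimen clinical cohort (75 GCB,
75 ABC) with the factor's expression shifted up in GCB and planted
target correlations of |r| = 0.6; and an essential-gene list overlapping
40% of the positively regulated targets plus a 5% decoy rate among nulls.

Defaults: 2,000 genes on 4 chromosomes, one gene per 50 kb slot (the
spacing guarantees that promoter windows, enhancer anchors and background
peak positions of different genes cannot collide, which is what makes the
planted truth exact); 40 + 40 promoter targets, 10 + 10 distal targets,
100 indirect genes; |log2FC| = 1. Counts are negative binomial with
log-normal baselines (target genes floored at a clearly expressed level —
a knockdown-responsive target is by definition an expressed gene),
per-line modulation (SD 0.2 on log2), ±20% library-size jitter, and
dispersion 0.05 — replicate-level variability of a cultured cell line;
clinical cohorts run several-fold higher, and the clinical matrix is
simulated separately as correlated Gaussians on the log scale. At
dispersion 0 the counts degrade to Poisson, which the tests check by
moments.

All randomness flows from one mandatory seed, with fixed offsets deriving
the per-stage streams (layout/peaks, counts, clinical, sequences), so a
bundle is byte-reproducible and any single stage can be regenerated
standalone. `validate_bundle()` re-reads an emitted bundle and re-asserts
every construction invariant from the files alone.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: read-level artifacts (mapping bias,
duplicates), peak-caller behavior (peaks are inputs here), fragment-level
ChIP signal shape, correlated gene-gene expression structure, batch
effects in clinical cohorts, annotation mismatches between assays (mixing
genome builds, e.g. hg38 expression against GRCh37 peak coordinates, is
not supported: the pipeline requires one shared annotation and implements
no liftover), and cell-type transfer error in interaction maps borrowed
from a different cell type.

## Problem sizes and numerical choices

The default validation scale — 2,000 genes end-to-end, 5,000 genes for
null calibration, 1,000 peaks × 200 genes for interval-oracle
equivalence, 150 specimens for the clinical screen — keeps every check
comfortably inside a single-CPU desk run while leaving Monte-Carlo error
small relative to the margins tested. Tolerances: OLS-limit agreement to
1e-8; enumeration-oracle agreement to 1e-9 or better; calibration bands
follow binomial sampling error at the stated sizes. Fisher's exact test
is conservative at small counts, so its null rejection rate is bounded
above by, not equal to, the nominal level — the dichotomization
calibration test asserts exactly that.

Known limitations: no per-transcript promoter mode beyond the gene-level
collapse; no interaction-score modeling; no survival or subtype-beyond-2×2
analyses; ORA assumes independent genes, as ORA always does.
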