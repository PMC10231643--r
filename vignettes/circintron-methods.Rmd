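---
title: "Models and methods behind circintron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circintron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circintron)
```

## The scientific problem

Bulk transcriptomes of post-mortem brain can be ordered along an ordinal
neuropathological scale (the Braak neurofibrillary-tangle stages, 0 for
aged-matched control through VI). Three RNA-level phenomena change along
that axis and are quantified here:

1. **Intron retention.** Some polyadenylated transcripts keep one intron.
   The per-sample statistic is the *percent intron retention*,
   $$\mathrm{PIR} = 100 \cdot \frac{EI}{EE + EI},
   \qquad EI = \tfrac{1}{2}(EI_{5'} + EI_{3'}),$$
   where $EE$ counts exon–exon junction reads skipping the intron and
   $EI_{5'}, EI_{3'}$ count reads crossing the two exon–intron boundaries.
   Averaging the two boundary counts (rather than summing) keeps
   PIR = 50 when exon–intron read flux equals exon–exon flux; the source
   wording is ambiguous on this point, so the choice is documented here and
   PIR is strictly increasing in $EI$ either way.
2. **Circular RNAs.** Back-splicing joins a downstream donor to an upstream
   acceptor; reads across the back-splice junction (BSJ) align as split
   reads whose genomic order is inverted relative to their query order.
   circRNA abundance is quantified relative to the linear transcript
   (junction ratio $c/(c+\ell)$, typically about 1%).
3. **A-to-I editing.** ADAR editing reads out as A>G mismatches. The
   *editing index* of a read pool is $\sum g_i / \sum d_i$ over qualifying
   adenosines ($g$ = G calls, $d$ = coverage), computed separately for
   BSJ-supporting (circular) and colinear (linear) reads; the linear pool
   doubles as the control for DNA variants.

Screening against stage uses Spearman correlation with average-rank ties; a
feature "passes" at $|\rho| \ge 0.8$. Group contrasts (combined low stages
vs combined high stages) use the ratio of group means with pseudocount 0.5,
a two-sided Welch t-test on log2 values, and the screening rule
FC > 1.5 (either direction) with raw p < 0.05; BH-adjusted values are
reported alongside because the screening rule itself uses raw p.

## Coordinates, strand, containers

All internal coordinates are 0-based half-open; conversion to the 1-based
conventions of GTF and SAM happens only in the readers and writers.
Features are kept in reference orientation; sequence-dependent operations
(splice-site windows, SRE scans, ORFs, editing) reverse complement
internally for minus-strand genes. Gene models live in a `gene_models`
object (tibbles of transcripts, exons, derived introns); alignments in a
`read_placements` tibble with one row per reference block, carrying the
query-order rank (from soft-clip geometry) that distinguishes colinear
splicing from back-splicing, and per-block aligned bases for mismatch
pileups.

## The synthetic-data generator

The generator emits the study conditions: seven samples, one per stage
0–6; per-gene true PIR either trending linearly 0 to 0.6 across stages or
flat at 0.3; circular/linear abundance ratio 0.01; circular-pool editing
rising threefold (0.02 to 0.06) across stages with the linear pool flat at
0.02; uniform substitution errors (default 0.001), no indels. Genes are
3–8 exons (80–300 bp) with GT..AG introns of 100–2,000 bp, roughly a third
of genes on the minus strand, and about 30% of sufficiently long introns
carry an embedded 300 bp Alu-like motif (a synthetic constant, not a real
repeat consensus). Two constraints go beyond those ranges so the
statistics are measurable at 150 bp read length: the designated retained
intron is drawn 300–1,500 bp (intron-body reads must fit inside), and the
two exons forming each gene's back-splice circle are at least 150 bp
(back-splice segments and editing-site windows must fit).

Because the study's circRNA libraries are RNase R-treated, the profile has
an `rnase_r_enrichment` factor (default 40): it multiplies the *emitted*
circular read count without changing the underlying 1% abundance ratio.
Tests that recover the abundance ratio set it to 1; tests that need
editing-index precision raise it, mimicking deeper circular coverage.

Per-sample circular counts are Poisson with mean
`circ_fraction x read_depth x stage multiplier x enrichment`. A junction
read of a retained intron is exon–intron with probability
$q = 2p/(1+p)$ so that the averaged-numerator PIR recovers the true $p$ in
expectation. Each output file draws from its own seeded stream
(`seed + file index`), so regenerating one component leaves the others
byte-identical.

What the generator does **not** emulate — and what green tests therefore do
not establish about real data: realistic nanopore error profiles,
fragment-size effects, indels, multi-isoform genes, cassette-exon events
(PSI is exercised on constructed junction reads instead), overlapping
genes, and genuine Alu-driven back-splice biology (motifs are placed, not
mechanistic).

## Numerical and threshold choices

* Detection defaults: `min_overhang` 8 bp, `min_ei` 2, body coverage
  >= 0.5, >= 10 junction reads; all exposed as arguments and in the
  pipeline config. "Expressed gene" for the introns-per-gene rate means
  >= 10 junction reads over its introns in that sample.
* Long-read validation is strict: an intron validates only with **more
  than** 10 polyA long reads containing the whole intron in one contiguous
  block (single molecules report exon–intron structure directly, so
  partial coverage does not count).
* BSJ calling: segments >= 15 bases, both ends within 2 bp of annotated
  splice sites (annotation-consistent mode), >= 2 supporting reads.
* Editing: site depth >= 5; sites within 3 bp of block ends excluded;
  positions with G fraction > 0.9 in the linear pool of every sample are
  masked in both pools as homozygous-variant surrogates. Candidate
  *sites* (the site-level report) additionally require >= 2 G calls at an
  edited fraction of >= 1% in at least one sample — the fraction guard
  keeps deep coverage of sequencing-error noise from being called as
  editing. Two normalizations are emitted: the aggregate per-sample index
  over all covered adenosines (primary for trend screening) and per-site
  fractions at candidate sites (primary for effect sizes such as the
  stage-0 to stage-6 fold increase, which the all-adenosine index would
  dilute with never-edited positions).
* The 2x2 chi-square applies Yates' continuity correction by default —
  that is the convention of the R function the original screening used,
  and the printed Alu p-value (7.79e-207) reproduces only with it. The
  tail probability is computed in log space, so p-values far below double
  underflow remain exact.
* Ward clustering uses `hclust(method = "ward.D2")` on Euclidean
  distances (the minimum-variance Ward variant on unsquared distances) and
  the dendrogram is seriated deterministically by mean expression, since
  raw `hclust` leaf order leaves each merge's orientation arbitrary.
* Local alignment (exon orthology) is Smith–Waterman with match +2,
  mismatch -3, gap open -5, gap extend -2 per base; identity counts
  matches over aligned columns, coverage is aligned query bases over query
  length, applied strictly (> 70% and > 50%) in both directions of an RBH
  pair. Ties on best-hit score break by identity, then lexicographic id.
* Splice-site strength is a position-weight-matrix log2-odds score versus
  a uniform background (5' window 3 exonic + 6 intronic bases, 3' window
  20 intronic + 3 exonic covering the polypyrimidine tract), with the PWM
  estimated from the input models' introns (pseudocount 0.5) when no
  matrix is supplied. This is a transparent stand-in scorer; only
  *relative* comparisons between intron classes are meaningful.
* Rolling-circle translation uses the standard genetic code, AUG starts
  only, and a default budget of 4 full passes (three passes restore the
  frame whenever $L \bmod 3 \neq 0$); protein masses are average-isotope
  residue masses plus one water, the quantity compared to gel sizes.

## Statistical design of the recovery tests

Problem sizes were chosen for test power: detection recall/precision runs
at junction depth 2,000 per intron; the PIR stage-trend property runs 20
seeds at depth 2,000 in a counts-only generator mode; editing-rate
recovery uses enriched circular coverage so per-site binomial intervals
are tight.

One property needs more samples than the study design provides. For a
flat (uncorrelated) linear editing pool, the null distribution of
Spearman's rho over 7 samples gives $P(|\rho| \le 0.5) \approx 0.76$ —
no sequencing depth changes this, because ranks of exchangeable noise are
uniform. A per-seed requirement of "circular $\rho \ge 0.8$ and linear
$|\rho| \le 0.5$" therefore cannot hold in 90% of seeds at $n = 7$. The
trend-separation test instead uses 3 replicates per stage (21 samples),
the smallest design in which the joint requirement has comfortably more
than 90% probability; the generator default remains the study's 7
samples.

## Known limitations

* The BSJ caller is annotation-consistent by design and does not
  reconstruct full-length circRNA isoforms; internal structure is only
  reported as the junctions observed inside BSJ-supporting reads.
* TMM normalization is replaced by library-size scaling plus the junction
  ratio; both are stored, and between-sample comparisons in the tests use
  the junction ratio, which is invariant to uniform per-sample scaling.
* Welch's t-test on log2 values stands in for the external quantifier's
  differential model in stage contrasts.
* The pileup assigns gene strand per contig; on references with multiple
  overlapping genes per contig, editing calls near overlaps would need a
  per-read gene assignment instead.
* With 2 samples per group and count-scale noise, the stage contrast has
  limited power; regulated-circRNA counts on small synthetic runs are
  conservative.

## Reading the outputs

`run_pipeline()` writes per-intron PIR tables, stage correlations, a BED
of validated introns, circRNA quantifications and contrasts, editing site
tables/indices/trends, plus `report.json`; every number in the report is
re-derivable from the TSVs, and the test suite includes that audit.
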