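# circintron

Quantitative analysis of three RNA-level readouts that change along an
ordinal neuropathological scale (Braak stages 0–6) in staged bulk brain
transcriptomes:

* **Retained introns** — detected from spliced short reads by combining
  exon–intron junction reads with intron-body coverage; quantified as
  percent intron retention,
  `PIR = 100 · EI / (EE + EI)` with `EI = (EI5′ + EI3′)/2`,
  screened for stage correlation (Spearman, |ρ| ≥ 0.8), and validated
  with polyadenylated long reads (strictly more than 10 single molecules
  carrying the whole intron in one block).
* **Circular RNAs** — back-splice junctions called from split reads whose
  genomic order is inverted relative to query order, quantified against
  the linear transcript (junction ratio `c/(c+ℓ)`, typically ~1%),
  stage-contrasted (fold change > 1.5, p < 0.05, Welch on log2 values),
  and ranked against a reference circRNA.
* **A-to-I editing** — A>G mismatch pileups split into circular
  (BSJ-supporting) and linear read pools; per-sample editing index
  `Σg/Σdepth` over qualifying adenosines; the linear pool doubles as the
  DNA-variant control.

Supporting modules cover intron characterization (Alu content with a 2×2
chi-square, splicing-regulatory-element base coverage, PWM splice-site
strength, relative position), reciprocal-best-hit exon orthology for
conserved retained introns, rolling-circle translation of circular ORFs
with predicted protein masses, and a synthetic-data generator that emits
genomes, GTF models, SAM libraries and truth tables for every statistic.

## Worked example

A full synthetic run — generate a staged dataset, detect and validate
retained introns, call and quantify circRNAs, compute editing trends:

```r
library(circintron)
report <- run_pipeline(list(
  outdir = "run1", seed = 7,
  profile = list(n_genes = 6, read_depth = 120, long_read_depth = 30)
))
```

which logs:

```
simulate: 6 genes, 7 samples
intron: 6 detected, 6 validated, 3 stage-correlated
circ: 6 BSJs, 0 regulated
editing: circular rho 0.96, linear rho -0.11
report written to run1/report.json
```

Reading the report: all 6 designated retained introns are detected and
long-read validated; the 3 genes whose true PIR rises with stage pass the
|ρ| ≥ 0.8 screen while the flat genes do not; every gene's back-splice
junction is found; and the circular-pool editing index recovers the
planted threefold rise (ρ = 0.96 across stages) while the flat linear
pool shows no trend. The planted stage-increasing circRNAs reach their
~3x fold changes in `circ_regulated.tsv`, but with only two samples per
stage group the Welch test stays at p ≈ 0.1, so none clear the
FC > 1.5 & p < 0.05 rule — the two-vs-two contrast is deliberately
conservative. Per-intron PIR tables, circRNA quantifications and editing
site tables are written as TSV next to the report, and every number in
`report.json` can be recomputed from them.

Individual steps are exported (`count_junction_reads()`, `compute_pir()`,
`detect_bsj()`, `quantify_normalize()`, `pileup_editing()`,
`editing_index()`, `translate_circular()`, ...) — see the methods
vignette (`vignettes/circintron-methods.Rmd`) for the models, parameter
defaults and their rationale.

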