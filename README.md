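# titrationBench

Cross-platform evaluation of transcriptional profiling — microarrays and
RNA-seq side by side — using an RNA titration mixture design and
probe-mapping-directed *transcript patterns*.

## The problem

Platform comparisons are confounded when the compared entities measure
different things: a 3'-biased probe sees only some of a gene's
transcripts, while a whole-transcript probeset or an exon count sees
others. This package implements an evaluation methodology that removes
that confounder and quantifies platform performance on a design with a
known answer:

* **Titration design.** Two pure RNA sources, `AGO` and `BMO`, are mixed
  so pure B is titrated into A at 1:4, 1:16 and 1:64 (one part A per
  *n* total parts), giving source-B percentages 0, 75, 93.75, 98.4375
  and 100 %. Every gene's expected abundance is linear in the mixture
  fraction *f*: `f·e_B + (1−f)·e_A`.
* **Transcript patterns.** Probes are filtered for unique, full
  alignment, then annotated with the exact transcript set whose exon
  union fully contains them. A (gene, transcript set) targeted by at
  least one feature on *every* platform is a transcript pattern — the
  strictest comparison level. Member features are summarized per
  pattern with a one-step Tukey biweight on log2(value+1).
* **Metrics.** Signal range and 99th-percentile signal-to-background
  (with a *quasi-background* for counts built from genes detected only
  in mixtures); fidelity of signal to the titration (fraction of
  features with |r| > 0.5 against the mixture fraction); average
  absolute fold-change `max(r, 1/r)` over the four contrasts and its
  enhancement by detection calls or pattern restriction
  (`(refined − baseline)/baseline × 100`); cross-platform fold-change
  compression `(1 − slope) × 100` from OLS regression of log2 ratios;
  and a four-way concordance classifier (compressed / opposite /
  overestimate / concordant) against ΔΔCt qRT-PCR fold-changes.

A fully parameterized synthetic study generator (annotation, probes,
expression with planted compression exponents, noise scales and noise
genes) makes every stage testable against known ground truth.

## Worked example

```r
library(titrationBench)

design <- canonicalTitrationDesign()
100 * bmoFraction(design)
#>     AGO  AG1BM4 AG1BM16 AG1BM64     BMO
#>  0.0000 75.0000 93.7500 98.4375 100.0000

study <- simulateStudy(nGenes = 2000, seed = 42)

## fidelity of raw signal to the titration (reference array)
titrationFidelity(study$matrices$arrayA, design)
#> FidelityResult: 68.3% of 1907 evaluable features with |r| > 0.5

## quasi-background of a sequencing platform from its noise genes
quasiBackground(study$matrices$seqA, design)
#> [1] 7.16

## normalize, collapse replicates, fold-changes, compression vs arrayA
norm <- lapply(study$matrices, function(x)
  if (valueKind(x) == "count") cpmNormalize(x) else quantileNormalize(x))
coll <- lapply(norm, collapseReplicates, design = design)
fc   <- lapply(coll, buildFoldChangeTable, design = design)
ref  <- log2Ratio(fc$arrayA)[, "BMO"]
sapply(setdiff(names(fc), "arrayA"), function(p)
  fcCompression(ref, log2Ratio(fc[[p]])[, "BMO"])$compression)
#> arrayB arrayC arrayD   seqA   seqB
#>   59.0   62.7   76.6   24.0   37.7

## the worked enhancement example: 5.42 -> 8.88 folds
fcEnhancement(5.42, 8.88)
#> [1] 63.83764
```

The fidelity line says 68 % of expressed features track the titration
with |Pearson r| > 0.5 on the reference array at its default noise
level. The compression vector recovers the planted platform behavior:
the power-law-compressed arrays lose ~60–77 % of the reference's log2
fold-change (exponent plus background effects), the sequencing
platforms ~24–38 %.

`runPipeline(config, outdir)` chains all stages (simulate or load →
patterns → preprocess → signal metrics → fold-change → concordance) and
writes TSV tables plus a byte-reproducible `summary.json`; see
`?runPipeline` and the vignette in `vignettes/` for the full
methodology.

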