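# missplice

Quantifying alternative-splicing mis-regulation from junction counts:
differential PSI analysis, microexon classification, odds-ratio
enrichment, RNA-binding-protein motif scanning, and covariate
dose–response — with a ground-truth simulator so the whole pipeline is
testable end to end.

## Who this is for

Transcriptomics analysts who already have rMATS-style per-event
inclusion/skipping junction-count tables (bulk or pseudobulk RNA-seq) and
want to ask the downstream questions: which events and genes are
mis-spliced between conditions, are microexons disproportionately
affected, are disease gene sets over-represented, do candidate
RNA-binding-protein motifs (e.g. the MBNL YGCY family, or the SRRM4
acceptor-side UGC site) sit in the introns flanking the responsive exons,
do two datasets change the same events in the same direction, and does
per-sample mis-splicing burden track a dose covariate such as CTG repeat
length.

## The statistics at the core

* **PSI** per event and sample from length-normalised junction counts,
  `PSI = (I/lI) / (I/lI + S/lS)`, with a per-sample coverage floor below
  which the value is missing rather than zero.
* **Differential splicing**: `ΔPSI = mean PSI(case) − mean PSI(control)`
  with a two-sided label-permutation test on per-sample PSI (exhaustive
  and exact when ≤ 10,000 label assignments exist, Monte-Carlo with
  add-one smoothing otherwise), BH FDR per event type, and the decision
  rule `|ΔPSI| > 0.1 & FDR < 0.05` (strict inequalities).
* **Microexons**: SE events with a 3–33 nt alternative exon, bounds
  inclusive.
* **Enrichment**: 2×2 tables tested with an enumerated two-sided
  Fisher's exact test; odds ratio `(ad)/(bc)` with Haldane–Anscombe 0.5
  correction on zero cells and a Woolf 95% CI; BH FDR across each batch
  of gene sets.
* **Motif grammars**: gapped degenerate patterns such as `YGCYGCY` and
  `YGCY(N)0-5YGCY`, scanned with all overlapping matches and gap
  realisations inside ≤ 500 nt intronic windows abutting the alternative
  exon's splice sites; presence/absence feeds the same 2×2 machinery.
* **Burden vs covariate**: per-sample mean `|PSI − control mean PSI|`
  over a chosen event subset, correlated with a numeric covariate
  (Pearson r, t-distribution p).

The methods vignette (`vignettes/missplice-methods.Rmd`) documents the
models, conventions, numerical choices and limitations.

## Worked example

Simulate a 500-gene study (8 cases vs 8 controls, ~200 junction reads
per event) with effects planted into one designated 100-gene set at odds
ratio 4 and MBNL-style motifs planted downstream of responsive exons
(70% foreground vs 20% background), then run the analysis:

```r
library(missplice)

cfg <- simConfig(seed = 42, nGenes = 500, coverageMean = 200,
                 enrichedSetSize = 100, enrichedSetOR = 4,
                 enrichedSetBaseRate = 0.2, nSets = 37,
                 motifFgProb = 0.7, motifBgProb = 0.2)
sim <- simulateDataset(cfg)
sim$se
#> SplicingExperiment with 991 events and 16 samples
#>   event types: SE=684 MXE=105 A5SS=80 A3SS=88 RI=34
#>   microexons (3-33 nt SE): 42
#>   groups: case=8 control=8

res <- diffSplicing(sim$se, seed = 42)
sum(res$isMisSpliced)            # 122 flagged (122 planted)

g <- misSplicedGenes(res)
en <- geneSetEnrichment(g$misSpliced, g$universe, sim$geneSets)
head(en, 1)
#>          name  a  b  c   d oddsRatio ciLow ciHigh  pValue     fdr
#> SET_ENRICHED 39 83 61 317      2.44  1.53   3.90 0.00025 0.00951

fg <- res$eventID[res$eventType == "SE" & res$isMisSpliced]
bg <- setdiff(res$eventID[res$eventType == "SE" & !is.na(res$fdr)], fg)
motifEnrichment(sim$se, fg, bg, sim$genome,
                c("YGCYGCY", "YGCY(N)0-5YGCY"))
#>   a  b   c   d oddsRatio ciLow ciHigh   pValue
#> 54 28 115 487      8.17  4.96   13.5 2.39e-17
```

Reading the output: 122 of 991 events pass `|ΔPSI| > 0.1, FDR < 0.05`;
the designated gene set tops the 38-set enrichment batch (OR 2.44, CI
excluding 1, FDR 0.0095); and mis-spliced skipped exons carry planted
YGCY-family motifs in their flanking introns far more often than
background exons (OR 8.2).

A dose covariate propagates into per-sample burden:

```r
cfg2 <- simConfig(seed = 7, nGenes = 500, coverageMean = 200,
                  covariateName = "CTG", nSets = 0, withGenome = FALSE)
sim2 <- simulateDataset(cfg2)
res2 <- diffSplicing(sim2$se, seed = 7)
psi <- computePsi(sim2$se)
cd  <- colData(sim2$se)
ctg <- setNames(cd$CTG, rownames(cd)); ctg <- ctg[!is.na(ctg)]
covariateBurdenCorrelation(
  psi, rownames(cd)[cd$group == "control"],
  res2$eventID[res2$isMisSpliced], ctg)[c("r", "p", "n")]
#> $r [1] 0.998   $p [1] 9e-09   $n [1] 8
```

The whole workflow can also be driven from one YAML file via
`runPipeline()`, which writes provenance-stamped TSVs for every stage
(see `?runPipeline`).

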