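---
title: "Models and methods behind missplice"
author: "missplice authors"
date: "`r Sys.Date()`"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind missplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missplice)
```

# Scope

`missplice` quantifies alternative-splicing mis-regulation from
junction-count tables of the rMATS dialect: percent-spliced-in (PSI)
estimation, replicate-aware differential splicing with a mis-splicing
decision rule, microexon classification, odds-ratio enrichment machinery
(gene sets, microexon disproportion, cross-dataset overlap, DPSI sign
concordance), a gapped degenerate motif grammar scanner for RNA-binding
protein sites around skipped-exon splice sites, and per-sample
mis-splicing burden correlated with numeric covariates such as CTG repeat
length. A fully specified synthetic-data generator with recorded ground
truth makes every stage testable without any external download.

Read alignment, junction counting from reads, transcript quantification,
differential expression and CLIP-seq processing are out of scope; counts,
genome sequence, gene sets and covariates are inputs.

# PSI and the splicing data model

For one event in one sample with inclusion-junction count $I$,
skipping-junction count $S$ and effective form lengths $l_I, l_S$ (the
number of junction spans supporting each isoform, e.g. 2 and 1 for a
skipped exon),

$$\mathrm{PSI} = \frac{I/l_I}{I/l_I + S/l_S}.$$

A sample must carry at least `minReads` (default 10) junction reads on
the event for a PSI value; below that the value is *missing*, not zero —
zero skipping reads are informative, absence of coverage is not. The
default floor is deliberately conservative and configurable; with typical
coverage of ~100 junction reads it discards only a small tail of events.

Data live in a `SplicingExperiment`, a `SummarizedExperiment` subclass
with `inclusion` and `skipping` assays, event annotation (type, gene,
0-based half-open genomic intervals of the alternative and flanking
exons) in `rowData` and the sample sheet in `colData`. All internal
coordinates are 0-based half-open; conversions happen only in readers and
writers (rMATS `exonStart_0base`/`exonEnd` columns are already in this
convention and are ingested unchanged; GTF-style 1-based input is
converted with `coordsTo0Based()`).

# Differential splicing

For a case/control comparison the per-event effect is
$\Delta\mathrm{PSI} = \overline{\mathrm{PSI}}_{case} -
\overline{\mathrm{PSI}}_{control}$ over informative samples, so
case-specific exon exclusion is negative. Significance comes from a
two-sided label-permutation test on per-sample PSI: exhaustive over all
distinct label assignments when there are at most 10,000 of them (the
test is then exact), otherwise Monte-Carlo with `nPerm = 9999` draws and
add-one smoothing $(1 + \#\{|T^\pi| \ge |T|\})/(n_{perm}+1)$, under a
mandatory seed recorded in the output metadata and file headers. The
permutation test is distribution-free and exact at small $n$; it replaces
likelihood-based event models deliberately, trading some power for
transparent calibration, and it is *not* an isoform-level model.

An event is **mis-spliced** when $|\Delta\mathrm{PSI}| > 0.1$ *and*
BH FDR $< 0.05$, both inequalities strict, so a DPSI of exactly 0.1 is
never called. FDR is computed within each event type (SE, MXE, A5SS,
A3SS, RI) separately by default, mirroring the per-type tables of the
upstream quantifiers this format comes from; a pooled mode
(`fdrScope = "joint"`) is available because the choice is genuinely open —
per-type is the default since consumers of per-type tables almost always
correct per file.

A practical consequence of exact permutation p-values worth knowing: with
3 versus 3 replicates there are only 20 label assignments, the smallest
achievable p-value is 0.05, and no BH-adjusted value can fall below 0.05
— a 3v3 design cannot produce mis-splicing calls under this rule. That is
faithful to how exact tests behave at minimal replication; the package's
default simulated design therefore uses 8 case and 8 control replicates,
where the Monte-Carlo permutation resolution (about $10^{-4}$) supports
the decision rule.

A **microexon** is an SE event whose alternative exon is 3–33 nt long,
bounds inclusive; events of other types are never microexons. A gene is
mis-spliced when at least one of its events is; the gene universe for
enrichment is every gene with at least one FDR-evaluable event.

# Odds-ratio enrichment machinery

All enrichment questions reduce to a 2×2 table. The two-sided Fisher
p-value is computed by direct enumeration over the feasible cell range at
fixed margins, summing hypergeometric point probabilities not exceeding
the observed one within relative tolerance $10^{-7}$ — the conventional
tie rule, with the tolerance stated because floating-point ties are
otherwise unstable. The odds ratio is the sample cross-product ratio
$(ad)/(bc)$ with a Woolf log-scale 95% interval
$\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$; when any cell is
zero, 0.5 is added to all four cells first (Haldane–Anscombe). The
correction policy is configurable (`on-zero` default, `always`, `never`)
because different downstream conventions exist; cross-product plus Woolf
was chosen as the transparent, hand-checkable default.

Table conventions, fixed and worth stating exactly:

* *Gene sets*: foreground = mis-spliced genes, background = the rest of
  the detected universe (foreground excluded); sets are intersected with
  the universe before tabulation; BH FDR across the batch of sets tested
  together; output ordered by descending OR.
* *Microexon disproportion*: foreground = mis-spliced SE events
  (optionally restricted to a gene set), background = **all**
  FDR-evaluable SE events including the foreground — this mirrors the
  "x% of all detected SE vs y% of mis-spliced SE" comparison and slightly
  attenuates the OR relative to an excluded-background design.
* *Overlap*: $(|A\cap B|, |A\setminus B|, |B\setminus A|,
  |U \setminus (A\cup B)|)$ over an explicit universe.
* *Concordance*: over shared events, the fraction with equal DPSI sign,
  and among those the fraction negative in both; zero or missing DPSI is
  excluded from sign classification.

Cross-species gene matching defaults to case-insensitive symbol identity
(symbols are uppercased at ingestion); an explicit two-column ortholog
table can be applied with `mapSymbols()` since ortholog inference is not
this package's business.

# Motif grammars and splice-site windows

RNA-binding-protein sites such as the MBNL high-affinity motifs
`YGCYGCY` and `YGCY(N)0-5YGCY` are expressed as *grammars*: IUPAC blocks
separated by bounded gaps (`(N)min-max`, `(N)k`, `N{min,max}`); `U`
equals `T`. The scanner reports **all** matches — overlapping ones and
every distinct `(start, end)` gap realisation — deterministically ordered
left-to-right, shortest first. Offsets are 0-based half-open (BED-style)
in the scanned sequence. Scanning is sense-strand only, because the
pre-mRNA is single-stranded; minus-strand genes are reverse-complemented
at extraction, never during scanning.

Windows are anchored at the alternative exon of SE events: up to 500 nt
of intron immediately upstream of its 3'SS and downstream of its 5'SS,
truncated at the neighbouring constitutive exon, never overlapping an
exon. Upstream/downstream are transcript-relative, hence mirrored on the
minus strand. Only the two introns abutting the alternative exon are
used (not the distal splice sites of the flanking exons) because the
mechanistic literature on MBNL-responsive exons centres on the intron
directly downstream of the regulated exon; a wider four-window layout can
be emulated by scanning the flanking exons' windows separately.

Motif *enrichment* is presence/absence: an event is positive when any
grammar hits in either window (hit counts are available for diagnostics
but the 2×2 test is defined on presence). The background excludes the
foreground. The SRRM4-style acceptor-side predicate reports a `TGC`
whose 3' end lies within offsets −25..−6 of the 3'SS on the intronic
side, an operationalisation of "approximately 15 nt upstream"; both the
window and the unit of the MBNL enrichment (events, here) are
parameters, since neither convention is universal.

# Covariate correlation

The per-sample mis-splicing burden of a case sample is the mean over
informative events of $|\mathrm{PSI}_s - \overline{\mathrm{PSI}}_{ctrl}|$
for a chosen event subset. The per-sample statistic had to be defined
here (group-level DPSI does not decompose uniquely); deviation from the
control mean is the simplest choice that reduces to $|\Delta\mathrm{PSI}|$
in expectation, and it is recorded prominently in output metadata.
Developmental series use the earliest time point as reference, so burden
grows as splicing matures. Correlation is plain Pearson with the
$t$-distribution p-value on $n-2$ degrees of freedom; when two paralogous
regulators are to be used as one covariate, their summed expression is
the default and individual paralogs remain available.

# The synthetic-data generator

`simulateDataset()` draws a complete study whose statistical structure
mirrors a bulk splicing experiment:

* events per gene $1 + \mathrm{Poisson}$, type mixture
  SE/MXE/A5SS/A3SS/RI = 0.70/0.10/0.08/0.08/0.04, 5% of SE exons from the
  microexon range;
* per-event per-sample total junction reads
  $\mathrm{NB}(\mu = 100, \text{size} = 10)$; inclusion counts
  beta-binomial with precision 50 around the length-adjusted inclusion
  fraction $\mu = \psi l_I/(\psi l_I + (1-\psi) l_S)$ — beta-binomial
  rather than binomial to emulate between-replicate biological
  overdispersion, with precision $\infty$ recovering the pure binomial
  for exactness checks; effective lengths derive from the junction
  structure (SE 2:1, MXE 2:2, A5SS/A3SS 1:1, RI 2:1) so the
  length-normalisation path is exercised non-trivially;
* true effects on 10% of events, $|\Delta\mathrm{PSI}| \sim U(0.15,
  0.5)$ with random (or forced-negative) sign; optionally concentrated in
  one designated gene set at a target odds ratio, or on microexons at a
  target disproportion OR (the planting rate is solved from the target of
  the measurable 2×2, and infeasible targets are rejected before
  sampling);
* genes on both strands 50/50, each event with a real two-flank
  exon/intron cassette on a synthetic chromosome; motif instances planted
  at recorded window offsets with separate foreground/background
  probabilities;
* an optional per-case-sample dose covariate (e.g. CTG repeat length,
  default range 200–800) scaling each sample's effect size by
  $v_s/\max v$.

Default problem sizes in the package's own validation runs are a few
hundred to a thousand genes and 8v8 samples, with 20 seeds per recovery
question and 50 for null calibration — large enough for stable odds
ratios, small enough that the whole validation suite runs on one CPU in
minutes.

One deliberate idealisation: outside planted sites, synthetic intron and
exon backbone sequence is depleted of the `GC` dinucleotide. Random DNA
contains a YGCY-class match in nearly every 500 nt window, which would
make presence/absence enrichment unidentifiable in a toy genome; real
introns do carry such background, so the synthetic motif tests
demonstrate correctness of the scanner and of the 2×2 machinery, not
genome-scale signal-to-noise. Other things the generator does not
emulate: intron-length and GC-content distributions of real genomes,
correlated events within a gene, coverage that depends on expression,
batch effects, and paired or covariate-confounded designs. Passing the
recovery tests therefore shows the estimators and decision rules behave
as designed under their own assumptions — not that any particular
biological dataset will yield a given OR.

# Numerical choices and degenerate inputs

* Permutation ties count as extreme (`>= obs − 1e−12`), so identical
  groups give $p = 1$ and the exact test never undershoots.
* Fisher tie tolerance $10^{-7}$ relative; enumeration is over the exact
  feasible range, so tables with zero margins degrade gracefully to
  $p = 1$.
* Zero cells: Haldane–Anscombe 0.5 on all four cells, flagged
  `corrected`; fully degenerate tables (an empty margin) are flagged
  `degenerate` and reported rather than dropped.
* Events informative in no sample are dropped with a warning; an event
  with one empty group keeps missing $p$ and is excluded from FDR.
* Missing count fields in input tables are missing samples, never zeros.
* Zero-length introns yield no scanning window (warning); introns
  shorter than the window truncate it.
* Gene sets are deduplicated and uppercased at parse time; a set
  spanning the whole universe yields a corrected, degenerate-flagged OR
  instead of an error.

# Limitations

The permutation test conditions on per-sample PSI and ignores count-level
uncertainty within a sample, so very unbalanced coverage between samples
is reflected only through the missingness rule. No covariate-adjusted or
paired differential model is provided. Gene-set enrichment uses an
unmatched background (no gene-length or expression matching). Motif
scanning is pattern-based with no affinity scoring or secondary-structure
context, and CLIP evidence enters only as optional interval annotations.
The human–mouse overlap unit is the gene symbol unless an ortholog table
is supplied; event-level overlap across species is not attempted.
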