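---
title: "Methods: hypoxic regulation of the coding and non-coding transcriptome"
author: "hypoxtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypoxic regulation of the coding and non-coding transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hypoxtx` re-implements, as a tested and reusable pipeline, an integrative
analysis of how low oxygen reshapes both the coding and the non-coding
transcriptome, and of the role of hypoxia-inducible factor (HIF) in driving
that response through release of promoter-paused RNA polymerase II
(RNApol2). The pipeline covers:

* priority-based ("sequential database") assignment of transcribed features
  to RNA classes (rRNA, tRNA, snRNA, miRNA, piwiRNA, mRNA, lncRNA) with
  class-specific low-abundance filtering;
* counts-per-million normalisation, per-contrast log2 fold-changes and
  class-wise box-plot summaries;
* discovery of non-annotated transcripts from unexplained stranded
  coverage, their split into intergenic and antisense loci, CpG-island
  detection near their putative promoters, an ORF-based coding-potential
  score, and co-/counter-regulation calls for sense/antisense pairs;
* assignment of HIF-1/HIF-2 ChIP peaks to the nearest expressed promoter,
  distance and class summaries, and a weighted running-sum gene-set
  enrichment statistic with a permutation null;
* metagene profiles, the RNApol2 travelling ratio, pause-summit
  localisation, condition contrasts of the travelling ratio, and the
  classification of hypoxic induction into pause release versus de novo
  recruitment;
* a seeded simulator that generates a miniature genome, annotation, count
  matrices, peak sets and coverage tracks with planted, recoverable
  effects, standing in for the original cell-line datasets.

Everything is driven by `run_pipeline()` over a `pipeline_config()`; each
stage reads and writes plain-text artifacts (GTF, BED, bedGraph, TSV,
JSON) so any stage can be rerun in isolation.

# Statistical procedures

## Normalisation and fold-change

Raw counts are normalised to counts per million (CPM),
$\mathrm{cpm}_{ij} = 10^6 c_{ij} / \sum_i c_{ij}$, and contrasts are
summarised as $\log_2\!\frac{b + p}{a + p}$ with pseudocount $p = 0.5$ CPM.
CPM with a pseudocount replaces a negative-binomial differential testing
framework deliberately: every downstream conclusion in scope (class-wise
direction, ranking for enrichment, dependence calls) uses only the
direction and ordering of fold-changes, which CPM preserves *provided
library composition is approximately balanced between conditions*. This
assumption is stated, not checked: strongly asymmetric designs would need
a trimmed-mean or median-ratio normalisation. Class summaries use type-7
(linearly interpolated) quantiles; box-plot statistics differ between
conventions, so the choice is fixed and documented.

## siRNA dependence calls

For each HIF-bound transcript the knockdown contrasts (each siRNA versus
the control siRNA, in hypoxia) are thresholded at $\delta = 0.5$ log2
units: suppression by the HIF-1α siRNA alone calls `HIF1`, by the HIF-2α
siRNA alone `HIF2`, by both `both`, otherwise `none`. The threshold is a
package convention (the original heat-map presentation had no numeric
cut-off) and is exposed as configuration.

## Gene-set enrichment

Transcripts are pooled across classes and ranked by hypoxic induction
(ties broken by mean abundance, then identifier, so the ranking is
deterministic). Walking down the ranking, set members add
$|s_i|^p / N_R$ (with $N_R$ the summed member weight) and non-members
subtract $1/(N - N_h)$; the enrichment score is the signed extremum of
the running sum and the leading edge is the set membership at or before
it. Because the design has single libraries per condition there are no
replicate samples to permute, so the null distribution uses random
gene-label sets of equal size; the p-value is
$(1 + \#\{|ES_\pi| \ge |ES|,\ \mathrm{sign}(ES_\pi) = \mathrm{sign}(ES)\})
/ (1 + B)$ with $B = 1000$ permutations by default, under a caller-supplied
seed.

## Peak-to-promoter assignment

Distance is measured from the peak summit to the transcription start site
(TSS) of the nearest transcript that survived abundance filtering,
reported signed in transcript orientation (negative = upstream) and
absolute for thresholding; a 2.5 kb cut-off separates promoter-proximal
from distal peaks. Summit-to-TSS was chosen over edge-to-edge because the
summit best localises binding. Equidistant TSSs resolve toward the more
abundant transcript, then the smaller identifier.

## Travelling ratio and induction modes

For each transcript longer than 330 bp the promoter density is the mean
RNApol2 signal per bp in TSS−30..TSS+300 (transcript orientation) and the
body density the mean over TSS+300..TES; the travelling ratio (TR) is
their quotient. The windows follow the convention in which the travelling
ratio was originally defined; the source analysis printed no windows, so
they are configuration. Pause release lowers the TR, so the per-gene shift
is $\Delta\log TR = \log_2 TR_{hyp} - \log_2 TR_{norm}$, compared between
direct HIF targets (peak within 2.5 kb) and distal controls (no peak
within 1 Mb) by a Wilcoxon rank-sum test (normal approximation with tie
correction, implemented in the package and cross-checked against exact
enumeration in the tests). Induction modes compare promoter and body
densities between conditions with a 0.1 signal/bp pseudocount: body fold
≥ 2 with promoter fold < 1.5 is pause release; body fold ≥ 2 with
promoter fold ≥ 2 is de novo recruitment; anything else — including the
deliberately ambiguous 1.5–2 promoter band — is "unchanged". The 2× and
1.5× thresholds quantify regimes the source described qualitatively and
are configuration.

## Novel transcripts

The assembler is a single-exon coverage merge: bases at or above
`min_depth` on a strand, not covered by same-strand annotation, merged
across gaps of at most `max_gap` (100 bp), discarding candidates shorter
than `min_length` (200 bp). A graph-based isoform assembler is
intentionally out of scope — the downstream classification, not isoform
structure, is what this pipeline exercises. A candidate's putative TSS is
its 5′-most covered base. Candidates overlapping nothing are intergenic;
candidates overlapping annotation only on the opposite strand are
antisense (attached to the largest-overlap sense partner); any same-strand
overlap discards the candidate. CpG islands follow the
Gardiner–Garden–Frommer convention (window 200 bp, G+C ≥ 0.5,
observed/expected CpG ≥ 0.6 with
$O/E = \mathrm{CpG} \cdot L / (C \cdot G)$, merged maximal runs re-tested
as a whole); a promoter flag is set when an island lies within 1 kb of the
putative TSS (inclusive). Coding potential is the longest forward-frame
ORF (ATG through stop) as a fraction of transcript length, with < 0.3
treated as non-coding; this is a deliberate proxy for a full
coding-potential classifier and its threshold is configuration.
Sense/antisense pairs with both |log2FC| ≥ δ are co- or counter-regulated
by sign agreement, otherwise unclassified.

# The simulator

The generator emulates the statistical structure of the original
ribosome-depleted directional RNA-seq + ChIP experiment at desk scale:

* **Genome and annotation.** Four chromosomes of 2.2 Mb; 940 public
  transcripts in six classes with realistic length ranges (mRNA
  2–20 kb down to small structural RNAs of 70–300 nt). Public transcripts
  are placed without overlap on either strand so that unstranded ChIP
  signal at a gene reflects that gene; real genomes nest genes (miRNAs in
  introns, overlapping UTRs), which is a stated simplification. Only the
  planted antisense loci overlap another transcript.
* **Class-specific regulation.** Per-transcript log2 fold-changes are
  normal around class means (+0.3 mRNA/lncRNA, +0.2 miRNA, −0.5 snRNA,
  −0.4 tRNA, −0.3 piwiRNA) with SD 0.6. The SD was fixed a priori so that
  the weakest class mean is ≥ ~2 standard errors of a class median at the
  default class sizes — a recovery benchmark must keep its own planted
  directions identifiable — while still producing multi-fold individual
  changes in both directions, as observed in each class.
* **Library composition.** Baseline abundances are log-uniform with
  class-specific ranges in which the down-regulated structural classes
  (snRNA/tRNA) carry a large share of library mass, as they do in real
  ribosome-depleted total RNA. This keeps the hypoxic and normoxic library
  sizes within a few percent of each other, so the CPM assumption above
  holds by construction; the residual composition shift is ~0.02 log2
  units.
* **HIF targets and peaks.** Targets are drawn from the strongly induced
  upper tail (planted log2FC ≥ 1.2, i.e. fold ≥ 2.3) of mRNA/lncRNA, get
  baselines from the upper abundance range, a dependence label (HIF1,
  HIF2 or both) and one peak per responsible factor with its summit within
  2.5 kb of the TSS. Distal background peaks (> 3 kb from every TSS) are
  added per factor to reach the configured distal fractions (0.5 and 0.7).
  The last chromosome carries no peaks and no targets, providing the
  "> 1 Mb from any peak" control group at desk scale.
* **Knockdown.** The matching siRNA retains `1 − knockdown_efficiency`
  (default 10%) of the HIF-attributable log2 induction. A transcript
  labelled `both` requires both factors, so either siRNA alone removes the
  whole attributable induction; the control siRNA equals hypoxia in
  expectation. Counts are negative binomial with a common dispersion of
  0.02, typical of a homogeneous cell line; single libraries per
  condition, as in the original design (replicates are configurable).
* **Coverage.** Noise-free kernels: RNApol2 is a Gaussian pause peak
  (SD 35 bp) centred 42 bp downstream of the TSS, strand-aware, plus
  uniform gene-body signal starting at +300 bp (the travelling-ratio body
  window) proportional to condition expression. At pause-release targets
  the hypoxic body rises while the pause peak stays at its normoxic
  height; at de novo targets both start near zero in normoxia; at all
  other genes promoter and body scale together, so their TR is unchanged —
  indirect regulation is planted as TR-neutral. H3K4me3 mirrors RNApol2
  with a broader kernel shifted 100 bp further downstream; DNase is a
  fixed promoter kernel identical in both conditions. Deterministic
  kernels make by-construction checks (equal pause summits, identical
  DNase) exact; Poisson-like ChIP noise is a realism the generator omits.
* **Novel loci.** 37 intergenic and 54 antisense loci (the totals the
  discovery stage should report), absent from the public annotation but
  transcribed in the stranded coverage. A CpG-island sequence (high G+C,
  CpG-rich) is planted within 1 kb upstream of the TSS of an
  exactly-rounded 55% of them (50 of 91). The background sequence is
  CpG-suppressed (80% of CpG dinucleotides rewritten, G+C 0.4), as
  methylation–deamination suppresses CpG in real genomes — without this,
  uniform random DNA itself satisfies the island criteria and the island
  finder would not be exercised meaningfully.

Determinism: every stochastic choice derives from the configuration seed;
two runs with the same configuration produce byte-identical files, which
the test suite asserts at the md5 level.

What passing recovery tests do **not** show: robustness to sequencing
noise in coverage, to unbalanced library composition, to nested or
spliced gene structure, to isoform-level assembly, or to peak-calling
uncertainty (peaks are inputs here).

# Numerical and design choices

* Coordinates are 0-based half-open internally (BED convention); GTF is
  converted on read/write. TSS of a − strand transcript is `end − 1`.
* The class priority order (structural RNAs before long RNAs) is a
  convention: the sequential-mapping figure it mirrors does not print its
  database order. It is configuration and recorded in provenance.
* Default abundance thresholds are mean raw count ≥ 10 (classes with
  median length < 200 nt) or ≥ 50 (longer classes), boundary inclusive;
  the original thresholds were drawn, not printed.
* The assembler's `min_depth` default (0.02) sits below the faintest
  simulated transcript's coverage; with real data it should be set from
  the depth distribution.
* Empty classes are omitted from summaries with a warning; transcripts
  shorter than the body window are skipped by the travelling ratio with a
  warning; a zero body density flags the ratio as undefined rather than
  dividing by zero.
* Problem sizes for the bundled validation (a ~8.8 Mb genome, ~1000
  transcripts, ~50 peaks per factor, 1000 permutations) were chosen so the
  full pipeline runs in well under a minute while leaving every planted
  effect several standard errors from its decision boundary.

# Known limitations

Single-exon assembly only; no isoform or polyadenylation analysis; no
dispersion estimation or false-discovery control (fold-change direction
and rank carry the class-level conclusions); unstranded ChIP signal at a
locus hosting an antisense transcript convolves both genes' signal — the
one place where the simulator's planted truth is deliberately not fully
recoverable; CPM normalisation assumes balanced composition, as discussed
above.
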