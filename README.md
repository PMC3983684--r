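# hypoxtx

Integrative analysis of the hypoxic coding **and non-coding**
transcriptome, and of how hypoxia-inducible factor (HIF) activates
transcription through release of promoter-paused RNA polymerase II
(RNApol2).

Cells answer low oxygen by remodelling transcription far beyond mRNAs:
long non-coding RNAs, miRNAs and structural small RNAs are all regulated,
in class-specific directions, and many of the induced transcripts are
direct HIF targets. `hypoxtx` packages that analysis for anyone working
with stranded RNA-seq count matrices, ChIP peak sets and coverage tracks:
regulatory genomicists who want a tested, seeded, end-to-end re-analysis
pipeline rather than a pile of one-off scripts.

## What it computes

* **RNA-class assignment** — features are assigned to classes
  sequentially by priority (rRNA → tRNA → snRNA → miRNA → piwiRNA → mRNA
  → lncRNA, same strand only), ribosomal features are diverted, and
  low-abundance transcripts are filtered with class-specific thresholds.
* **Expression summaries** — CPM normalisation,
  `log2((b + 0.5) / (a + 0.5))` fold-changes for hypoxia and HIF-siRNA
  contrasts, class-wise box statistics, deterministic induction ranking,
  and HIF-dependence calls (`HIF1` / `HIF2` / `both` / `none`) from the
  knockdown contrasts.
* **Novel transcripts** — single-exon assembly of unexplained stranded
  coverage; intergenic/antisense classification; Gardiner–Garden–Frommer
  CpG islands ( `O/E = CpG·L/(C·G)` ≥ 0.6, G+C ≥ 0.5, ≥ 200 bp ) near
  putative promoters; ORF-fraction coding potential; sense/antisense
  co-/counter-regulation.
* **HIF peak association** — summit-to-TSS assignment to the nearest
  expressed promoter, distance histograms with the >2.5 kb distal
  fraction, class shares, and a weighted running-sum gene-set enrichment
  score with a gene-label permutation p-value.
* **RNApol2 pausing** — TSS-anchored metagene profiles (FPKM-normalised),
  the travelling ratio `TR = density(TSS−30..TSS+300) /
  density(TSS+300..TES)`, pause-summit localisation, the per-gene shift
  `Δlog TR = log2 TR_hyp − log2 TR_norm` compared between direct HIF
  targets and >1 Mb distal controls (internal tie-corrected rank-sum
  test), and pause-release vs de novo recruitment calls.
* **A seeded simulator** (`sim_config()`, `simulate_dataset()`) that
  generates a miniature genome, annotation, counts, peaks and coverage
  with planted, recoverable effects — the stand-in for the original
  MCF-7 datasets, and the substrate for the package's recovery tests.

## Worked example

```r
library(hypoxtx)

cfg <- pipeline_config(seed = 1)      # simulation + every stage parameter
run_pipeline(cfg, "hypoxia_run")      # simulate → classify → express →
                                      # novel → hif → pausing → report

read_table("hypoxia_run/class_fc_summary.tsv")
```

```
  rna_class   n   min     q1  median      q3   max
1    lncRNA 189 -1.04 -0.119  0.3488  0.7971 1.873
2     miRNA 120 -2.42 -0.288  0.0713  0.6017 1.808
3      mRNA 355 -1.97 -0.165  0.3418  0.7671 2.053
4   piwiRNA  60 -1.89 -0.830 -0.4679  0.0795 1.433
5     snRNA  80 -2.20 -0.878 -0.5095 -0.0500 1.640
6      tRNA  80 -1.93 -0.799 -0.3396  0.0107 0.997
```

Median hypoxic log2 fold-change is positive for mRNA, lncRNA and miRNA
and negative for the structural small-RNA classes — the planted
class-specific regulation, recovered from the simulated counts.

```r
nov <- read_table("hypoxia_run/novel.tsv")
table(nov$category); mean(nov$cpg_within_1kb)
```

```
 antisense intergenic
        54         37
[1] 0.5494505
```

All 91 planted non-annotated loci are recovered and split exactly into 37
intergenic and 54 antisense transcripts; 55% carry a CpG island within
1 kb of the putative promoter.

```r
jsonlite::read_json("hypoxia_run/pausing_summary.json")
```

```
{"pause_summit_offset_bp":45,
 "tr_shift":{"per_group":[
   {"group":"direct_targets","n":17,"median_dlogTR":-1.3629},
   {"group":"distal_controls","n":157,"median_dlogTR":0.0000}],
   "w":365,"z":-4.9116,"p_value":9.03e-07}}
```

The RNApol2 metagene peaks 45 bp downstream of the TSS (one 10-bp bin
from the planted +42), and the travelling ratio of direct HIF targets
drops in hypoxia (median Δlog TR ≈ −1.36, rank-sum p ≈ 1e-6 against
distal controls) while controls do not move — pause release, not new
recruitment, carries the induction.

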