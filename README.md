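# chiprx

Quantitative analysis of spike-in normalized (ChIP-Rx) histone-modification
ChIP-seq, built for studies of oncohistone-driven epigenome reprogramming —
in particular H3K36M-mutant cells, where genome-wide H3K36me2/me3 loss and
enhancer inactivation depend on *where* the mutant histone is incorporated
(H3.3-like: active genes, introns, intergenic loci and enhancers;
H3.1-like: exons of repressed genes).

It is aimed at computational epigenomics work where peak sets, coverage
tracks and spike-in read counts already exist (or are simulated) and the
question is quantitative: how much signal was lost, where, and how do the
changes relate to mutant-histone occupancy, enhancer states and gene
expression.

## What it computes

* **ChIP-Rx normalization.** Per-sample factor `f = 1e6 / N_spike` (reads
  per million spike-in reads), turning raw binned counts into RRPM
  (reference-adjusted reads per million). Genuine global losses survive
  RRPM but are invisible to per-million-target scaling; the package keeps
  both so the rescue is demonstrable. Samples without spike-in (e.g.
  mutant-histone ChIP) are depth-normalized to RPM, and every report
  records which scaling was used.
* **Interval algebra** on `GRanges`: overlap (≥ 1 bp, half-open), whole-peak
  and base-level subtraction, union-merge (gap-aware, book-ended intervals
  unite), nearest-TSS assignment (midpoint anchor, 500 kb window), and
  chromosome/length-matched shuffled nulls.
* **Enhancer pipeline.** Promoters = [TSS − 2 kb, TSS + 500 bp),
  strand-aware. Enhancers = H3K4me1 peaks not overlapping H3K4me3 peaks or
  promoters. States: H3K27ac+ → active; else H3K27me3+ → poised; neither →
  primed (dual-marked enhancers are active; their fraction is reported).
  Wild-type active enhancers whose mutant state is no longer active are
  *inactivated*, with `%inactivated = 100 · n_inact / n_active`.
* **Reprogramming statistics.** Common/unique peak decomposition with
  both-perspective Venn counts, genomic-element annotation
  (promoter > exon > intron > intergenic, midpoint rule), expression
  tertiles, per-state expression contrasts (Mann–Whitney, BH-corrected),
  inactivated-enhancer vs differential-expression association with
  `log2((FPKM_mut + 1)/(FPKM_wt + 1))` fold changes binned at 0/1/2/≥3
  enhancers, and Pearson correlations of Δmark vs mutant-histone occupancy.
* **Synthetic data.** `simulate_chiprx()` generates a toy genome,
  annotation, multi-mark coverage, peaks, spike counts, expression and DE
  tables with a complete ground-truth ledger (injected global depletion,
  locus-coupling constant, true enhancer states and inactivated sets), so
  the whole pipeline is testable offline.

## Worked example

```r
library(chiprx)
sim <- simulate_chiprx(sim_config(seed = 1))      # synthetic experiment
run <- run_chiprx(sim, chiprx_config(seed = 1))   # full analysis
print(run)
```

```
chiprx_run (config 638f0366 )
  wt   enhancers: 1041 active / 292 primed / 167 poised
  h33  enhancers: 467 active / 1101 primed / 532 poised
  h31  enhancers: 533 active / 1053 primed / 514 poised
  h33: 635/1041 WT-active inactivated (61.0%)
  h31: 573/1041 WT-active inactivated (55.0%)
  h33: r(dK36me2, occ) = -0.70 (n=1041); r(dK27ac, occ) = -0.85 (n=1041)
  h31: r(dK36me2, occ) = -0.70 (n=1041); r(dK27ac, occ) = -0.85 (n=1041)
```

Reading this: of 1,500 simulated enhancers the wild type classifies 1,041
as active; in the mutants most of those lose the active state (61% / 55%,
matching the generator's injected inactivation fractions), and the
per-enhancer H3K36me2 and H3K27ac losses correlate negatively with local
mutant-histone occupancy — the locus-dependence signature. The
dose–response of expression is in `run$assoc$h33$fc_bins`:

```
  bin n_genes median_lfc    mean_lfc
1   0      41 -0.1277154 -0.07029011
2   1      51 -0.7488555 -0.70645561
3   2      49 -1.3414266 -1.44150398
4 >=3      69 -1.7807977 -1.83921168
```

— genes assigned more inactivated enhancers are more downregulated.
`run_chiprx(..., out_dir = "run")` writes all tables (TSV, stamped with
the resolved config hash), Venn/summary JSON, and enhancer BEDs;
`make_report(run)` renders SVG panels.

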