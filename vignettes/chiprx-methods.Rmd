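---
title: "Methods: quantitative ChIP-Rx analysis of H3K36-methylation and enhancer reprogramming"
author: "chiprx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative ChIP-Rx analysis of H3K36-methylation and enhancer reprogramming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific setting

Lysine-to-methionine substitutions at H3 lysine 36 (H3K36M) act as dominant
inhibitors of H3K36 methyltransferases. Because the histone variant H3.3 is
deposited replication-independently — at actively transcribed genes,
enhancers and other intergenic loci — while canonical H3.1 is deposited
replication-coupled across the genome (and is retained at repressed,
exon-rich chromatin in the models considered here), the *same* point mutation
carried on the two variants can reprogram the epigenome differently: the
methylation loss is strongest *in cis*, at the loci where the mutant histone
is incorporated. `chiprx` implements the quantitative analysis that makes
this locus dependence measurable:

1. spike-in (ChIP-Rx) normalization, so that genome-wide losses are
   quantifiable at all;
2. per-interval densities and scaled metagene profiles;
3. enhancer calling, active/primed/poised classification, inactivation
   calls and enhancer-to-gene assignment;
4. peak-set decomposition into common/unique classes against
   chromosome- and length-matched shuffled nulls, genomic-element
   annotation, expression stratification, and Pearson correlation of mark
   changes against mutant-histone occupancy;
5. a synthetic-data generator with a complete ground-truth ledger, so every
   stage is validated end-to-end without external data.

## Spike-in normalization (RRPM)

Each ChIP reaction carries a fixed proportion of foreign-genome chromatin
(typically 1–5% drosophila). After alignment, reads are split into target
and spike-in counts, and each sample's scaling factor is

$$f = \frac{10^6}{N_{\text{spike}}},$$

the reads-per-million-spike-in convention. Multiplying raw per-bin counts
by $f$ gives **RRPM** (reference-adjusted reads per million). The factor is
a deterministic function of the spike-in count only; target totals are
recorded for reporting.

The defining property — and the reason per-million-target scaling is kept
alongside as the contrast — is the *rescue* of uniform global changes.
If a mutant genuinely halves a mark genome-wide, target reads halve while
the spike-in recovery is unchanged at fixed sequencing depth, so RRPM
densities halve too; per-million-target scaling renormalizes the loss away
and reports a ratio of ≈ 1. `simulate_chiprx()` injects exactly this
scenario, and the acceptance suite asserts that the RRPM ratio over
H3K36me2 domains recovers the injected multiplier within 0.05 while the
per-million ratio stays at ≈ 1.

One exception is deliberate: mutant-histone (H3K36M) ChIP is modeled
without spike-in, so those tracks are depth-normalized to reads per million
target reads (RPM). The scaling mode used for every report is recorded in
the run summary (`k36m_mode`), and both modes are available.

## Enhancer definitions

* **Promoters** are strand-aware windows from 2 kb upstream to 500 bp
  downstream of each TSS, clipped at chromosome ends.
* **Enhancers** are H3K4me1 peaks that do not overlap (≥ 1 bp) any H3K4me3
  peak or any promoter. Exclusion is *whole-interval*: a touching peak is
  dropped entirely, not trimmed. Base-level trimming is available through
  `subtract_intervals(mode = "base")` for sensitivity analyses.
* **States**: an enhancer overlapping an H3K27ac peak is *active*;
  otherwise one overlapping an H3K27me3 peak is *poised*; one lacking both
  is *primed*. Two labeling conventions circulate in the literature for the
  H3K27me3-marked class; this package consistently uses
  `poised = H3K27me3+`, and stamps the convention string into the
  classification output and the run summary so downstream consumers never
  have to guess.
* **Precedence**: an enhancer carrying both H3K27ac and H3K27me3 is classed
  active (active > poised). Because this rule is a genuine judgment call,
  the fraction of such dual-marked enhancers is always reported
  (`attr(, "ambiguous_fraction")`), making the rule's impact visible.
* **Inactivation**: each wild-type *active* enhancer is mapped by ≥ 1 bp
  overlap onto the mutant enhancer set. If any overlapping mutant enhancer
  is active it stays active (active > poised > primed when several
  overlap); if none overlaps it is *lost*. Inactivated means "mutant state
  is not active", and lost counts as inactivated — the natural reading when
  inactivation percentages are quoted against the wild-type active count.
* **Assignment**: enhancers are assigned to the gene whose TSS is nearest
  to the enhancer midpoint, within 500 kb; unassigned enhancers carry NA.
  The midpoint anchor is symmetric and deterministic; distance ties break
  to the lexicographically smaller gene id.

## Locus-dependence statistics

* `decompose_peaks()` splits two peak sets into common (≥ 1 bp overlap with
  the other set) and unique classes. With many-to-one overlaps the two
  "common" counts can legitimately differ, so Venn counts are reported from
  both perspectives rather than forcing a single middle number.
* `shuffle_intervals()` builds the matched null: one uniformly placed
  interval per input peak, same chromosome and same length, avoiding an
  exclusion set. Chromosome matching preserves local background better than
  genome-wide placement. Placement is rejection-sampled with a bounded
  retry count and fails loudly, naming the interval, rather than silently
  under-producing.
* `annotate_elements()` assigns each peak midpoint to exactly one of
  promoter > exon > intron > intergenic. Midpoint assignment avoids double
  counting boundary-spanning peaks; the fractions always sum to 1.
* `stratify_expression()` splits expressed genes into rank-based tiers
  (default tertiles) with gene-id tie-breaks, so the split is deterministic
  under ties; zero-FPKM genes go to the lowest tier.
* `delta_records()` + `delta_correlation()` compute, per interval, the
  change in a mark (condition B − condition A, same units) and the
  mutant-histone occupancy at the same interval, then the standard Pearson
  product-moment correlation with n reported. Fewer than 3 records or zero
  variance in either field is an error (r undefined), never an NA.
* Fold changes are `log2((FPKM_mut + 1)/(FPKM_wt + 1))`; the pseudocount
  guards zero FPKM. Genes are binned by their count of assigned inactivated
  enhancers at 0 / 1 / 2 / ≥ 3 by default (configurable via `fc_bins`).
* Location contrasts between interval groups use the two-sided
  Mann–Whitney (Wilcoxon rank-sum) test — robust to the heavy-tailed
  density distributions — with Benjamini–Hochberg correction across the
  contrasts of one analysis.

## Coordinates and numerical conventions

All file formats are 0-based half-open (BED convention); in-memory
intervals are `GRanges` (1-based closed) and the conversion happens only at
the parser/writer boundary, so there is a single internal convention and no
off-by-one drift. Overlap defaults to ≥ 1 bp and book-ended intervals do
not overlap; `min_bp` is exposed for sensitivity analyses. Pooling peak
calls from independent clones is union-then-merge (`merge_intervals`,
gap 0, which also unites book-ended intervals) — the most inclusive
deterministic reading of "pooled".

Interval densities are length-weighted means of the bins intersecting the
interval, with partial bins weighted by their overlap in bp; densities are
exactly invariant to bin refinement for bin-aligned intervals, and this is
asserted against a base-resolution oracle at 1e-9. Metagene profiles use
5 kb flanks at 100 bp bins and 100 equal body fractions by default (the bin
counts are conventions, not measurements, and are exposed); minus-strand
genes are orientation-flipped; genes shorter than the body bin count are
dropped and reported, never upsampled.

All randomness (shuffling, simulation) runs under an explicit seed through
an RNG guard that restores the caller's RNG state, so identical configs
give byte-identical outputs and a session's global RNG is never perturbed.

## The synthetic-data generator

`simulate_chiprx()` emits a toy genome (default 2 chromosomes × 5 Mb,
50 bp bins), ~300 non-overlapping genes with exon structure, strand and
log-normal FPKM (70% expressed), ~1,500 enhancers placed in intergenic
space near seeding genes, and per-mark, per-condition coverage, peaks,
spike-in counts, expression and DE tables. Conditions are wild type plus
two mutant-histone regimes: `h33` (occupancy at enhancers/intergenic loci
and introns of expressed genes, scaled by expression) and `h31` (occupancy
at exons of repressed genes).

Wild-type tracks are compartment base rates: H3K36me2 over expressed gene
bodies and broad (±2 kb) merged enhancer domains; H3K36me3 over expressed
gene bodies scaled by expression; H3K4me1 at enhancers; H3K4me3 and
H3K27ac at expressed promoters; H3K27ac at active enhancers; H3K27me3 at
poised enhancers and repressed gene bodies. Mutant H3K36me2/me3 rates are

$$\lambda_{\text{mut}} = \lambda_{\text{wt}} \cdot g \cdot
  (1 - k \cdot \text{occ}),$$

with $g$ the global depletion multiplier (default 0.5 in both mutants),
$k$ the locus-coupling constant (default 0.5, constrained to $[0,1)$ so
rates stay non-negative), and occ the mutant-histone occupancy normalized
to [0, 1]. H3K27ac at wild-type-active enhancers falls in proportion to
occupancy, and the most-occupied active enhancers form the inactivated
truth set (defaults 61% / 55% of wild-type active enhancers in h33/h31).
Mutant-specific redistribution domains (exons of repressed genes in h33,
introns in h31) create mutant-unique peaks; the top-occupancy quintile of
enhancer domains drops out of the mutant peak set, creating wild-type-unique
peaks. Genes acquire a true log2 fold change of −(effect size) per assigned
inactivated enhancer (the assignment used for the truth is the same
nearest-TSS rule the pipeline applies), plus an enhancer-independent
shifted subset and gaussian noise; DE statuses threshold the true fold
changes. Bin counts are Poisson by default, with an optional
negative-binomial dispersion.

Spike-in reads are simulated as a count, not placed coverage — the pipeline
consumes only the count. The count is proportional to sequencing depth and
the configured spike chromatin fraction, and deliberately *not* to the
mutant's depleted target yield: that asymmetry is the physical content of
spike-in normalization and is what makes the rescue property testable.

**What the generator does not emulate** — read-level artifacts (fragment
length, GC, mappability), peak-caller behavior beyond optional endpoint
jitter and dropout, diploid genotypes, replicate structure, and
inter-enhancer correlation. Passing recovery tests therefore demonstrates
the pipeline's correctness on data satisfying the model's assumptions, not
robustness to every failure mode of real ChIP-seq; the noisy peak mode
exists to observe graceful degradation, which is reported, not asserted.

## Problem sizes and runtime

The default configuration was chosen so a full simulate-plus-analyze cycle
runs in well under a minute on one CPU: ~1,000 wild-type active enhancers
for the correlation analyses (Pearson r has a standard error of ~0.02 at
that n under the default coupling), ~500 merged H3K36me2 domains for the
rescue ratio, and 10 Mb of genome at 50 bp bins. Unit tests use a smaller
1 Mb-per-chromosome configuration.

## Known limitations

* Venn "common" counts are perspective-dependent by construction; there is
  no single middle number when overlaps are many-to-one.
* Enhancer-to-gene assignment is nearest-TSS only; no chromatin-contact
  evidence is used.
* Whether densities should be computed over peaks, fixed windows or whole
  compartments is an analysis choice; the package computes over
  caller-provided interval sets and records which were used.
* The generator's enhancer-to-TSS distances are draw parameters; at the
  default gene density the *nearest* TSS is often closer than the seeding
  draw, so distance-recovery checks use a sparse-gene configuration where
  the two coincide.

## Minimal end-to-end example

```{r example}
library(chiprx)
sim <- simulate_chiprx(sim_config(seed = 1))
run <- run_chiprx(sim, chiprx_config(seed = 1), out_dir = "chiprx_run")
print(run)
summary(run)$rescue
make_report(run)
```
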