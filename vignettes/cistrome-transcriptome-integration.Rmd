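---
title: "Integrating cistromes with transcriptomes: methods and design notes"
author: "cistromeCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating cistromes with transcriptomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromeCT)
```

# The problem

A transcription factor's cistrome — the genome-wide set of its binding
sites (ChIP-seq) or the accessible regions that respond to its ligand
(ATAC-seq) — only matters insofar as it moves transcription. This
package implements the desk-side half of that question: given peak
sets, gene models, differential-expression (DEG) tables, gene-set
enrichment (GSEA) results, and patient expression cohorts, it
quantifies how strongly a cistrome couples to a transcriptome and which
coregulators shape that coupling. The motivating application is
vitamin D receptor (VDR) signaling in prostate cancer models and
cohorts stratified by genomic ancestry, but every function is generic
over the input tables.

# Peak-to-gene annotation

Peaks are annotated to genes when they overlap the gene body by at
least 1 bp, or when the gap between the peak and the gene span is at
most `window` bp (default 100 kb, the conventional regulatory
neighborhood used throughout the source analyses). Key choices:

* **Coordinates.** Everything is BED-convention (0-based, half-open) at
  the boundary and `GRanges` inside; conversion happens exactly once,
  in the constructors and readers. Touching intervals do not overlap.
* **Linkage is gap-to-gene-span, distance is midpoint-to-TSS.** The
  window applies to the gap between the peak and the whole gene span
  ("up and downstream, or within genes"), so a peak 100,000 bp from the
  gene end still links while 100,001 bp does not. The scalar `distance`
  reported per link — used for binning and for distance weights — is
  the signed bp from peak midpoint to the TSS, negative upstream on the
  gene strand. Two measures are needed because a single scalar cannot
  both honor the span-based annotation rule and feed a decay weight.
* **`window = 0` degenerates to body overlap only.** Under half-open
  coordinates a touching peak/gene pair has gap 0 without sharing a
  base; we resolve that corner by making `window = 0` mean "gene-body
  links only", which is also the variant the test suite pins down.
* **Zoning.** `within` = body overlap; `proximal` = `|distance|` at
  most 10 kb without body overlap; `distal` = the rest of the window.
  The 10-kb split is the conventional promoter-proximal cutoff; the
  sources never define one, so it is a config parameter
  (`proximal_cutoff`).
* **Strand** affects only the sign of `distance`, never linkage.
* **Nearest-gene mode.** The source analyses annotate "within 100 kb"
  in one place and "within 100 kb of the nearest gene" in another; the
  default links all genes in the window and `nearest_only = TRUE`
  restores the stricter reading (ties broken by gap, then `|distance|`,
  then gene id — deterministic).
* **Chromatin states.** Each peak takes the state with maximal bp
  overlap; exact ties go to the first state in a declared priority
  order, again for determinism.

# The wt-C-T score

For a differentially expressed gene $g$ with linked peaks $p$, the
weighted cistrome-transcriptome score is

$$\mathrm{wtCT}(g) = |\log_2 \mathrm{FC}_g| \sum_{p \in L(g)} s_p\, w_p,$$

where $s_p$ is the peak's significance ($-\log_{10}$ adjusted p,
capped at 50 so one extreme region cannot dominate a gene) and $w_p$ a
weight in $(0,1]$. The unweighted variant sets $w_p = 1$. The sources
describe the weighting only as "by the peak distribution (proximal
vs. distal)", citing the BETA family of regulatory-potential methods
whose common ingredient is a monotone distance decay. Two readings are
implemented:

* `decay` (default): $w_p = \exp(-\ln 2\,|d_p|/\lambda)$, a half-life
  decay on the midpoint-to-TSS distance with $\lambda$ = 10 kb (the
  proximal cutoff), and $w_p = 1$ for gene-body peaks. A peak exactly
  one half-life from the TSS counts half.
* `zone_proportion`: each peak is weighted by the fraction of its
  gene's links sharing its zone class (`within`/`proximal` pooled
  against `distal`), the literal "proportion of the peak distribution"
  reading.

Neither is asserted to be the original intent; the default is the decay
because it is the standard regulatory-potential form. Both satisfy
weighted $\le$ unweighted, and with $\lambda \to \infty$ the decay
variant converges to the unweighted score (tested to 1e-9).

**Aggregation and significance.** Scores are aggregated per stratum
(cell line, condition, or the chromatin state of the linking peaks — a
gene may appear in several strata via different peaks). The sources
assert significance without naming a test, so we use the
assumption-lightest option: a permutation null that shuffles stratum
labels across the (gene, label) rows, preserving the pooled score
distribution, with a one-sided empirical p
$(1 + \#\{\bar{x}^{null} \ge \bar{x}^{obs}\})/(B+1)$. With a single
stratum every permutation reproduces the observed mean and p is exactly
1. Default $B$ = 10,000 draws; a seed is mandatory.

# Overlap enrichment and printed-table conventions

* **Hypergeometric tail.** Cistrome-gene/DEG overlaps are tested with
  the upper-tail hypergeometric $P(X \ge k)$. The source note reads
  "lower.tail = FALSE", whose literal semantics in R is $P(X > k)$;
  enrichment of the observed count is clearly intended, so
  $P(X \ge k)$ is the default and `strict_tail = TRUE` restores the
  literal reading. The gene universe is never stated in the sources and
  defaults to all genes in the supplied gene model set (overridable);
  published log p-values are therefore not reproduction targets.
* **Thresholds are strict** (`>` as printed): `logPV > 1` with
  `absFC > 0.37` (cell DEGs) or `> 0.58` (serum miRNA), and
  `FDR < 0.1` with `|FC| > 1.3`. `absFC` values are taken as log2
  (2^0.37 ≈ 1.29 ≈ "FC > 1.3"); both parameterizations are exposed via
  `absfc_min`.
* **Rounding is half-up**, to one decimal where tables print decimals
  (85.65 → 85.7) and to whole percent where the text prints whole
  percents (12/33 → 36%). Base `round()`'s round-half-to-even would
  silently disagree with printed values.
* **Factor co-enrichment.** From a similarity-ranked dataset table,
  `fold_change = (count_topk/k)/(total_factor/total_datasets)` with
  k = 200 and a co-enrichment call above 1.2-fold; the ranking below
  position k is provably irrelevant and tested as such.

# Delta-NES divergence

For terms scored in two conditions, `delta = |NES_a − NES_b|` and a
term is *oppositely regulated* when delta exceeds 3. The printed
criterion is the delta alone, so a sign switch is recorded but not
required (`require_sign_switch = TRUE` adds the stricter reading, and
`signed = TRUE` reports the signed delta). "Significantly enriched in
both" is FDR < 0.1 per condition, the only significance level stated in
the GSEA context. The absolute-delta reading matches the published
example (−2.99 vs 1.28, delta 4.27 > 3).

# delta.corr coregulator screening

For TF $t$, targets $Y$ and coregulator $c$:
$$\mathrm{delta.corr}(c) = \overline{r(t, y)} - \overline{r(t, y \mid c)},$$
first-order Pearson partial correlations (one coregulator controlled at
a time, matching a one-bar-per-coregulator readout), averaged over
targets *before* differencing; the per-target matrix is available via
`per_target = TRUE` because the aggregation order is genuinely open and
both reductions derive from it.

Significance permutes $c$'s sample vector ($B$ = 1,000 default, seeded,
two-sided on delta.corr). Two design notes:

* **Sign.** delta.corr is positive when the coregulator *explains*
  shared TF-target variance, which requires $c$ to covary with the TF.
  A coregulator that adds variance to targets *independently* of the TF
  makes the partial correlation exceed the marginal one and delta.corr
  goes negative. The package's planted-recovery simulations use
  independent regulators (`tf_coreg_cor = 0`), so they verify two-sided
  detection, not the sign; set `tf_coreg_cor > 0` to emulate the
  positive values seen for chromatin coregulators in tumor cohorts.
* **Balanced groups.** Group contrasts are meant for equal sample
  sizes; `balance_groups()` performs the seeded subsampling. The
  contrast flags a coregulator "group-specific" when its permutation p
  clears 0.05 in exactly one group.

# The synthetic-data generator

`sim_config()` fixes the study conditions for every test; the defaults
are: a 2 × 20-Mb genome with 500 non-overlapping genes, 20%
stimulus-responsive; 2,000 peaks per condition, 70% placed within
100 kb of a responsive gene (each such peak is linkable *by
construction*), significances from a heavy-tailed gamma (shape 1.2,
scale 2) so a few peaks dominate sums and exercise the significance
cap; DEG tables with BH-adjusted p-values where responsive genes get
|log2FC| centred on 1.0 (about two-fold, a typical strong stimulus
response) and z-scores at 3 effect/noise units; a 211-term NES table
with 135 planted opposite terms (the published landscape's shape); and
a two-group cohort of 36 samples per group where each target is
`0.6·TF + 0.6·COREG1 + N(0, 0.5)` in group A and TF-only in group B —
unit-variance regulators with residual noise 0.5 give targets an
R² around 0.74, a realistic tightly-regulated module.

Everything is a pure function of the config (seed included): identical
configs give byte-identical files, and generated files round-trip
through the package readers.

**What it does not emulate** — and therefore what green tests do *not*
establish about sequencing data: read-level noise and peak-calling
uncertainty (significances are drawn, not estimated); correlated gene
placement, gene clusters and shared regulatory domains (genes are
uniform and disjoint); realistic chromatin-state grammar (states tile
chromosomes independently of peaks and genes); library-size and
batch structure in expression (samples are i.i.d. given the planted
model); and any dependence between the DEG table and the peak
placement beyond shared responsive-gene identities.

# Numerical and testing choices

* Empirical p-values use the add-one form $(1+b)/(B+1)$, never 0.
* Distance bins are half-open $[k w, (k+1)w)$; a distance exactly on an
  edge goes to the upper bin.
* Degenerate inputs: empty peak sets and strata yield empty/zero
  outputs, never errors; undefined percentages (0/0) are reported
  absent; collinear controls in partial correlations are errors.
* Report files carry a provenance header (package version, md5 of the
  analysis parameters — not of file paths — and the seed), so reruns
  with the same config and seed are byte-identical.
* Test problem sizes: oracle equivalences run at 200 peaks × 50 genes,
  universe ≤ 12 for exhaustive hypergeometric enumeration, and n = 80
  for residualization; calibration suites use 200 null screens (200
  permutations each) and KS uniformity at p > 0.01; power suites use 20
  repeats × 1,000 draws (wt-C-T, planted 2× inflation) and 50
  replicates × 500 permutations (delta.corr, planted β = 0.6 at
  n = 36). These sizes make the whole suite comfortably reproducible on
  a laptop while keeping binomial error on the asserted rates small.

# Limitations

The wt-C-T weighting's exact published form is unrecoverable from the
text; both implemented readings are declared package choices. Published
absolute wt-C-T magnitudes and hypergeometric log p-values depend on
full sequencing-scale inputs and unstated universes and are not
reproduction targets. delta.corr is first-order only — it is a
screening statistic, not causal mediation. The permutation nulls
assume exchangeability of genes across strata (wt-C-T) and of samples
(delta.corr); structured confounding (batch, ancestry within group)
must be handled upstream or via the covariate table.

```{r example}
# a two-minute end-to-end run on synthetic data
cfg <- pipeline_config(seed = 1, out_dir = tempfile("ct_demo"),
                       logpv_min = Inf, absfc_min = log2(1.3),
                       use_padj = TRUE, null_draws = 500,
                       permutations = 200)
cfg <- run_simulate(cfg, sim_cfg = sim_config(seed = 1, n_genes = 100,
                                              n_peaks = 300,
                                              chrom_length = 6e6))
run_annotate(cfg)
run_delta_nes(cfg)
read_tsv_report(file.path(cfg$out_dir, "delta_nes_summary.tsv"))
```
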