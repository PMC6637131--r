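---
title: "CNA calling and tumor purity from paired variant files: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNA calling and tumor purity from paired variant files: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnapair)
```

`cnapair` detects somatic copy-number alterations (CNAs) and estimates
tumor purity from the allele depths stored in a paired tumor–normal
variant file. This vignette is the package's account of the model, its
assumptions, the tunable parameters, and the design choices made where
the method left room for them.

## The signal model

A variant file from a tumor–normal pair records, at every called SNV, the
mutant-supporting and total read counts for both samples. Two independent
signals live in these counts:

* **Coverage.** The ratio of tumor to normal depth at a locus tracks the
  tumor's relative copy number there. Averaged over many sites, the ratio
  of a region at absolute copy number $C$ in a tumor of purity $p$ is
  $r = (pC + 2(1-p))/2$ relative to the diploid level.
* **Allelic balance.** At a germline-heterozygous site the normal B-allele
  frequency (BAF) is 0.5. A CNA carried by a cell fraction $x$ (signed:
  gain $x>0$, loss $x<0$) moves the tumor BAF to one of two cluster
  centers, $\frac{1+x}{2+x}$ and $\frac{1}{2+x}$, whose separation is
  twice the loss-of-heterozygosity $\mathrm{LOH} = |b_T - b_N|$.

The pipeline turns the first signal into segments and classes, and the
second into a purity estimate.

## Pipeline stages and parameters

### Filtering

An optional BED blacklist (0-based half-open) removes suspicious SNPs.
Records whose normal depth falls outside
$[\tilde{m}\cdot\texttt{min\_factor},\; \tilde{m}\cdot\texttt{max\_factor}]$
(inclusive; $\tilde{m}$ = median normal depth, supplied or computed) are
ignored; on chrX the `xmin_factor`/`xmax_factor` pair applies. Defaults
0.2/3.0 (autosomes) and 0.1/3.0 (chrX) bracket the normal-coverage
dispersion of typical 30–60× genomes while tolerating the halved male
chrX coverage; "outside the range" is read as strict exteriority, so the
bounds themselves survive. chrY and mitochondrial records are dropped:
the BAF model assumes two germline haplotypes.

Heterozygous sites are those with normal BAF in
$[\texttt{het\_baf\_min}, \texttt{het\_baf\_max}] = [0.30, 0.70]$ and
normal depth ≥ 10. The interval is a binomial argument, not a measured
constant: at depth 30–60 a true heterozygote (BAF 0.5) falls outside
[0.30, 0.70] in well under 3% of draws, while true homozygotes
essentially never fall inside. Both cutoffs are exposed in
`cna_config()`.

### Windows and the diploid baseline

Sites are binned into fixed 100-bp windows (window $i$ spans
$[100i+1, 100(i+1)]$); a window's tumor/normal coverage is the mean of
its sites' depths and windows without variants are ignored. At typical
WGS SNP spacing most windows hold a single site, so the window layer is
mainly a coordinate grid; its statistical value appears in deeper or
denser data.

Ratios are normalized so that diploid ≈ 1. With a user-specified
`diploid_region` the baseline is the median raw ratio there. Otherwise a
provisional segmentation is run and, among segments spanning ≥ 5 Mb, the
coverage-ratio mode whose het sites have the smallest median site-LOH is
taken as diploid (two retained haplotypes give balanced BAFs); ties go to
the mode covering the most bases, and with no ≥ 5 Mb segment the
genome-wide median is the fallback. The known failure mode is a
genome-wide duplicated tumor: the duplicated state is itself the
balanced-BAF mode, so automatic inference normalizes to it and the
profile reads as diploid — no read-depth method can detect this without
external information, which is exactly what the `diploid_region` override
is for (the package's tests reproduce both the failure and the rescue).

### Segmentation

Windows are segmented per chromosome by binary recursive partitioning of
`log2_ratio`, the regression-tree way: every candidate split is scored by
its reduction in the sum of squared errors (SSE), the best (leftmost on
ties) is taken, and recursion continues while both children hold
`min_windows` ≥ 5 windows and the reduction is at least
$\texttt{min\_gain} \cdot \mathrm{SSE}_{\text{chromosome}}$ (default
$10^{-3}$).

The reference point for `min_gain` is a deliberate design choice. Scored
against the *node* SSE, a $10^{-3}$ threshold accepts essentially every
split in noisy data — at 30× a single-site window has a log2-ratio sd of
≈ 0.37, so the tree fractures into `min_windows`-sized leaves whose means
scatter far beyond any reasonable merge tolerance. Scored against the
*chromosome root* SSE (the `cp` convention of CART/rpart), the threshold
scales with chromosome size and noise, which makes it self-penalizing:
pure-noise splits (whose best-split gain grows only like
$\log\log n$) are rejected, while megabase single-copy events at 30×
exceed it by orders of magnitude. This is what makes the caller robust to
the focal depth bursts of damaged libraries: a 1–10 kb burst contributes
too little SSE to justify a split and is absorbed, at the cost of reduced
power for genuinely focal (< 100 kb) low-amplitude CNAs — an accepted
property of a method whose informative sites are thousands of bases
apart.

Adjacent segments whose means differ by less than `merge_tol` = 0.1
(log2 units; half the smallest event the default caller flags) are then
merged iteratively, closest pair first, means recomputed
window-weighted. Classification converts $r = 2^{\overline{\log_2}}$ to
`seg.mean` $= r-1$ (0.5 per clonal copy) and `gmean` $= 2r$ (diploid
2.0; a clonal one-copy loss is 1.0 — the linear scale is used
consistently even though legacy descriptions of the gmean field disagree
internally about the loss values). Calls use
`call_tol` = 0.1 seg.mean units, half of a 20%-purity single-copy event.

### Purity

Only copy-neutral through single-copy segments are informative under the
two-population model: $x = 2\,\texttt{seg.mean} \in [-1, 1]$, with at
least `min_het_sites` = 10 heterozygous sites, autosomes only. For each
such segment the LOH is estimated as half the separation of the two
tumor-BAF clusters — a deterministic 2-center k-means (quantile-seeded)
on the site BAFs, with the median folded deviation $|b - 0.5|$ as the
unimodal fallback, capped at 0.5. Then
$y = \mathrm{LOH}(2+x) - |x|/2$ (CN-LOH fraction, clamped at 0, flagged
if meaningfully negative) and
$\text{purity} = |x| + y = \mathrm{LOH}(2+x) + |x|/2$, clamped to [0,1].

Per-segment estimates are clustered with 1-D Gaussian mixtures
(1–5 components, BIC-selected, via `mclust`, whose hierarchical
initialization is deterministic); the **sample purity is the highest
cluster center**. Copy-neutral segments without CN-LOH contribute a
low-lying noise cluster (k-means on a unimodal BAF cloud overestimates a
zero separation by roughly $0.8\sigma$, ≈ 0.05 at 60×, hence estimates
near 0.1) — taking the maximum center ignores it. Fewer than
`min_purity_segments` = 20 estimates yields `reliable = FALSE` and no
purity, matching the observation that most exome samples carry too few
eligible segments. The clustering consumes per-segment (not per-site)
estimates: segments are the model's exchangeable unit, and per-site
estimates would weight long segments quadratically.

Two documented biases follow from the model rather than the code: CNAs
confined to a subclone of fraction $f$ yield estimates near $f\cdot p$,
not $p$ (the package reproduces this on a 50% subclone simulation), and
samples without eligible CNA/LOH lesions yield no estimate at all.

## The simulator

`truth_profile()` fixes the study conditions: abstract chromosomes,
per-segment haplotype copy numbers $(c_A, c_B)$, clone fraction, CN-LOH
fraction, purity, and site densities. Defaults — 0.5 het plus 0.5
homozygous-alt sites per kb, 30× mean depth — correspond to the few
million usable SNPs per WGS pair that motivated the method, with sites
thousands of bases apart. Depths are Poisson around
$D\cdot T/2$ ($T$ = cell-averaged total copies), allele counts Binomial
around the cell-averaged B-copy fraction, which reproduces the analytic
BAF centers for single-copy events; `depth_model = "none"` gives rounded
expectations for exact output-semantics checks. `add_artifact_noise()`
multiplies tumor depths in 1–10 kb bursts (2/Mb, log-normal sdlog 0.5 by
default) by a common factor, preserving BAF — the fractured-genome
stressor.

What the simulator does **not** model: GC and mappability waves,
alignment artifacts, contamination of the normal, sequencing error in
allele counts, and linked (haplotype-phased) BAF noise. Passing tests
therefore demonstrate correctness of the method's arithmetic and its
robustness to depth artifacts, not performance on every real-library
pathology.

## Numerical choices and degenerate inputs

* Ratios are floored at $2^{-8}$ before `log2`, keeping homozygous
  deletions finite; windows with zero normal coverage are dropped.
* Split ties break leftmost; merging proceeds closest-pair-first, so a
  chain of near-equal segments collapses independently of input order.
* Segment LOH uses quantile-seeded k-means — no random restarts, so
  results are seed-independent; `estimate_sample_purity` falls back to a
  quantile-seeded k-means BIC scan only if the mixture fit fails, and a
  zero-variance estimate vector short-circuits to a single center.
* The ≥ 90% corroboration rule is evaluated in integer arithmetic, so a
  90-of-100 segment is corroborated and 89-of-100 is not, with no
  floating-point edge.
* Multi-allelic rows, indels and AD-less rows are skipped and counted;
  duplicated positions keep their first record.

## Problem sizes used by the test suite

The suite's end-to-end checks run on genomes scaled to keep the whole
suite around a minute while preserving the statistics that matter: 30-Mb
single-chromosome genomes (~30,000 sites) for exact output semantics;
five 42-Mb genomes at 60× (~42,000 sites each, 28 CNA segments of 600 kb,
~300 het sites per segment) for purity recovery at
$p \in \{0.3, 0.5, 0.7, 0.9, 1.0\}$ (recovered within ±0.05); 10-Mb
burst-noise genomes for the hypersegmentation guard (final segment count
≤ 1/10 of the fully grown tree's leaves at per-base F1 ≥ 0.9); and ≤
500-window sequences where the tree's breakpoints are checked against an
exhaustive SSE-minimizing changepoint search (±2 windows at noise
σ = 0.1).

## Known limitations

* Focal (< 100 kb) low-amplitude CNAs are below the design resolution.
* Genome-wide duplication is invisible to automatic baseline inference
  (override with `diploid_region`).
* Purity is biased toward the dominant CNA-bearing subclone and
  undefined for CNA-quiet samples; it assumes the diploid baseline is
  correct.
* Allele depths are trusted as written in the input; no re-genotyping or
  error modeling is attempted.
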