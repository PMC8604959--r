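---
title: "Methods: building a cRE atlas and mapping variants to genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a cRE atlas and mapping variants to genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`crev2g` implements a physical variant-to-gene (V2G) mapping pipeline for
multi-stage differentiation studies that profile chromatin accessibility
(ATAC-seq), promoter-focused capture interactions, and gene expression
(RNA-seq). The pipeline has three layers:

1. **Atlas construction.** Replicate peak sets are merged into a consensus
   set of open chromatin regions (OCRs), each OCR's accessibility is
   quantified per stage, and open OCRs are classified as promoter OCRs,
   promoter-interacting-region (PIR) OCRs, or non-PIR OCRs. Promoter and
   PIR OCRs — the OCRs annotatable to a gene — are the putative
   cis-regulatory elements (cREs).
2. **Count statistics.** Differential accessibility and expression between
   consecutive stages, with TMM normalization for expression and
   background-bin normalization for accessibility, plus trajectory
   clustering of the differential genes.
3. **Variant-to-gene mapping.** GWAS sentinel SNPs are expanded to LD
   proxies, proxies are intersected with stage-open OCRs, open proxies are
   connected to genes through two physical routes (a distal fragment in
   significant contact with a baited promoter, or residence in a baited
   promoter fragment), and candidate genes are filtered by expression.

All coordinates are 0-based half-open (BED convention) internally; 1-based
formats (GTF, variant positions) are converted at their readers.

# The atlas model

**Consensus and reproducibility.** Peaks from all replicates are merged
transitively wherever they overlap by at least 1 bp; abutting peaks are
not merged. A merged region is kept only if it overlaps peaks from at
least half of the replicates (rounded up). The reproducibility denominator
is per stage by default — a region reproducible in at least half of any
one stage's replicates survives — so that each stage's atlas is
self-contained even when stages have different replicate counts; a global
denominator is available via `build_consensus(mode = "global")`.

**Openness.** Accessibility is measured as FPKM:
`count / (length_kb * lib_size_millions)`, with the library size taken as
total mapped reads supplied alongside the counts (peak-restricted column
sums would overstate depth differences). An OCR is *open* in a stage when
its mean FPKM across that stage's replicates exceeds 1. The threshold is
the `fpkm_open` entry of `default_config()`.

**Classification.** Per stage, each open OCR receives exactly one class by
priority: `PromoterOCR` when it overlaps any promoter window (strand-aware
−1500/+500 bp around the TSS); otherwise `PIR_OCR` when it overlaps (≥1
bp) the other-end region of a significant interaction whose bait overlaps
a baited gene's promoter window; otherwise `NonPIR_OCR`. Interaction
significance is score > 5 (CHiCAGO-style scores are consumed as input,
never recomputed). Interactions are carried in ibed coordinates; a call
made at 4-fragment resolution spans its member fragments, so coordinate
overlap projects 4-fragment significance onto constituent single
fragments without a separate code path. Classification is stage-matched:
an interaction supports PIR status in the stage it was called in
(`significant_interactions(collapse_stages = TRUE)` gives the union
reading instead).

**Promoter windows.** The −1500/+500 bp window is applied on the gene
strand and clipped at position 0. Feature annotation
(`annotate_feature()`) uses the fixed hierarchy Promoter > 5'UTR > CDS >
3'UTR > first intron > other introns > intergenic; the first intron is the
intron adjacent to exon 1 on the annotated strand, and query strand is
ignored because ATAC peaks are unstranded.

# Count statistics

**Normalization.** TMM is implemented from its defining formula: M and A
values per gene against a reference sample (the one whose upper quartile
is closest to the mean upper quartile), two-sided trimming of 30% on M and
5% on A, and a precision-weighted mean of the surviving M values; factors
are re-centred to geometric mean 1. Ranks use first-occurrence
tie-breaking so that heavily tied inputs (e.g. two identical libraries)
still trim symmetrically. For accessibility, the same TMM machinery is
applied to read counts in 10-kb genome bins rather than to peak counts, so
factors track background coverage and are not driven by signal regions
(`background_bin_factors()`).

**Filtering.** Rows with median CPM below threshold across all samples are
removed before testing — 0.7 CPM for expression, 1.2 CPM for
accessibility by default; rows exactly at the threshold are kept.

**Differential test.** Two-group comparisons use a negative-binomial exact
test: counts are equalized to the geometric-mean effective library size,
a single common dispersion is estimated by the method of moments pooled
across rows (ratio-of-sums estimator, stable at small n), and the group
split of each row's total is tested conditionally (double-tail exact
probabilities; the binomial conditional in the Poisson limit). This is a
deliberate, fully specified engine for two-group contrasts; its contract
is checked by calibration (null type-I error inside the binomial
confidence band) and planted-effect recovery rather than numeric equality
with any particular GLM implementation. Calls require FDR < 0.05
(Benjamini–Hochberg) and |log2FC| > 1, with a prior count of 0.5 in the
fold-change to avoid infinities. Depth equalization makes results
invariant to per-sample depth rescaling up to pseudo-count rounding.
A known property of this design is that the realized false discovery
proportion under strong planted signal can exceed the nominal FDR
slightly, because the common dispersion pools signal and null rows; the
type-I error of the p-values themselves is calibrated.

**Trajectory clustering.** Differential genes are standardized per gene
(z-scores across samples) and clustered by agglomerative hierarchical
clustering; the tree is cut into six branches. The distance and linkage
are not dictated by the procedure's description, so the package uses the
common defaults Euclidean/complete, both configurable. Six clusters match
the six stage-restricted archetypes (enriched or depleted in exactly one
of three stages). Constant rows get a zero z-score with a warning.

# Variant-to-gene mapping

The filter chain is: sentinel → proxies with r² > 0.6 (sentinels always
count as their own proxy; sentinels absent from the reference panel
contribute nothing but are tallied) → proxies inside stage-open OCRs
(half-open point containment; 1-based positions converted internally) →
genes via two stage-matched routes:

* `distal_PIR` — the proxy's OCR overlaps the other-end region of a
  significant interaction whose bait overlaps a baited gene's promoter
  window; the bait gene is implicated.
* `bait_OCR` — the proxy's OCR overlaps the restriction fragment
  containing a baited gene's TSS; that gene is implicated directly.

Records are kept when the gene's stage-mean TPM exceeds 1. Duplicate
(trait, sentinel, proxy, gene, stage) tuples are collapsed, recording
every route that applied. Trait summaries count signals, panel
membership, unique proxies, per-stage open proxies in cis-interactions,
sentinels with such proxies, contacted genes per stage, and unique genes
across stages; the cross-trait table is an UpSet-style exclusive
decomposition. LD itself is out of scope: the proxy table with r² is an
input, and `ld_from_haplotypes()` exists only to derive r² for synthetic
haplotypes.

Each sentinel is summarized independently even when sentinels share
proxies, matching the convention that GWAS signals are reported as
independent loci. The pipeline requires a proxy to fall inside an open
OCR first — a proxy in a contacted fragment but outside any OCR is not
counted — because open chromatin intersection is the first step of the
chain.

# Enrichment statistics

* `hypergeom_test()` — upper-tail hypergeometric gene-set enrichment
  (`stats::phyper`), BH-corrected across sets. The default universe for
  pipeline use is the set of genes expressed (TPM > 1) in any stage,
  configurable, since the procedure itself does not fix one.
* `fisher_2x2()` — exact conditional test for marker-set enrichment.
* `permutation_region_overlap()` — length-preserving, within-chromosome
  uniform re-placement of every query region, 10,000 permutations by
  default, with optional exclusion of the longest fraction of each region
  set (1% in the published comparison this mirrors) because the longest
  peaks dominate overlap counts. The empirical p is
  `(1 + #{perm ≥ obs}) / (n_perm + 1)`. Two statistics are offered: the
  number of overlapping query regions (default, matching common practice)
  and total overlapping bases. At small region counts the count statistic
  is heavily tied, which makes its empirical p conservative rather than
  uniform; the base-overlap statistic is near-continuous and calibrates
  cleanly, so it is the right choice for null-calibration studies.
* `tf_site_enrichment()` — TF binding sites (purity > 0.7) are counted in
  foreground cREs versus permuted background sets drawn from non-PIR
  OCRs, matched exactly on the foreground's GC-decile × read-count-decile
  histogram (empty cells fall back to the nearest cell, with a message).
  This is an explicitly specified decile-matched permutation test; its
  contract is calibration-based, not equality with any external tool.

# The synthetic study design

`simulate_dataset()` generates a complete, self-consistent toy
differentiation study and a ground-truth manifest, so every stage of the
pipeline can be tested without downloads. The defaults emulate the study
design the pipeline targets:

* three stages (ESC → HP → HN) with 4/4/6 ATAC replicates and 3 RNA
  replicates per stage;
* a 2 × 1 Mb random genome digested at GATC (DpnII), giving ~256 bp
  fragments; genes every 30 kb with three exons, alternating strands;
* four planted OCRs per gene (promoter, distal PIR slot, non-PIR, closed)
  plus an irreproducible single-replicate decoy peak; replicate dropout
  at rate 0.15, capped so planted regions never fall below the half rule;
* negative-binomial counts (dispersion 0.05) around per-stage FPKM
  targets: 8 for open regions, 0.1 for closed, 6 vs 24 for the planted
  4-fold differential regions — chosen so that openness calls separate
  cleanly from the FPKM > 1 threshold at these depths;
* capture interactions from each gene's TSS fragment to its PIR-slot
  fragment(s): planted contacts score U(6, 12), decoys U(0.5, 4.9),
  flanking the score > 5 rule from both sides; some genes are contacted
  only at 4-fragment resolution, one pair only in HP;
* expression follows the six archetypes (TPM 60 vs 7.5, an 8-fold swing)
  plus flat genes at TPM 20 and planted not-expressed genes at TPM 0.3;
* three traits whose planted sentinel→proxy→OCR→gene links survive every
  filter, plus one decoy per failure mode and per trait: r² ≤ 0.6, proxy
  in closed chromatin, proxy in an uncontacted OCR, and proxy contacting
  a gene with TPM ≤ 1 — so each rejection path of the V2G chain is
  exercised individually;
* two TFs with binding sites concentrated in cREs and three null TFs.

All randomness flows from one seed; the same configuration is
byte-identical across runs. `validate_manifest()` re-derives the
pipeline-facing facts from the emitted files and fails naming the first
mismatch.

What the generator deliberately does **not** emulate: realistic LD block
structure (proxies are planted points, not haplotype draws), sequence
motif biology (TF sites are placed, not scanned), read-level data,
overdispersion heterogeneity across regions, GC bias, and copy-number or
blacklist artifacts. Passing recovery tests on this design therefore
demonstrates the correctness of the filter chain and the statistics'
calibration — not robustness to every pathology of real sequencing data.
The emitted TPM table carries the planted values with lognormal noise
rather than being re-normalized to a million per sample, because a
60-gene toy transcriptome would otherwise inflate every TPM by orders of
magnitude and make the TPM > 1 threshold meaningless.

# Numerical choices and scale

Problem sizes in the tests and the acceptance script are desk-scale by
design: a 2 Mb genome, 60 genes, 240 consensus OCRs, 2,000-row
calibration matrices, 199–2,000 permutations per test. These sizes keep
the full suite fast while leaving every code path identical to what a
genome-scale run would execute; nothing in the implementation depends on
the toy scale.

Degenerate inputs are handled explicitly: empty replicate lists, all-zero
background bins, zero library sizes and zero-length regions are errors;
constant-expression genes z-score to zero with a warning; TMM falls back
to factor 1 with a warning when trimming removes everything; monomorphic
variants give `NA` r². Ties in the exact test's double-tail probability
use a `1 + 1e-10` relative tolerance, the standard guard against float
jitter when summing probabilities "as extreme as observed".

# Known limitations

* The NB exact test assumes a single common dispersion; genes or regions
  with atypical dispersion are tested at the pooled value. Tagwise
  moderation is out of scope.
* PIR classification requires coordinate overlap with a contacted
  fragment; interactions whose other end lies outside every OCR
  contribute nothing, by construction of the filter chain.
* Bait-to-bait interactions are kept by default (a config flag could drop
  them); in the synthetic design they do not arise.
* The per-stage reproducibility rule means a region reproducible in one
  stage enters the consensus for all stages; its openness elsewhere is
  then decided by the FPKM rule, which is the intended semantic.
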