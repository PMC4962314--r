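---
title: "Deciding where GWAS risk SNPs act: chromatin-state enrichment by cell type"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding where GWAS risk SNPs act: chromatin-state enrichment by cell type}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromenrich)
```

## The problem

Most genome-wide-significant risk variants for complex diseases sit in
non-coding DNA. A risk-associated *index SNP* is rarely causal by itself: it
tags a haplotype carrying many correlated variants, any of which could be
the functional one, and the cell type in which that function plays out is
unknown. `chromenrich` implements a complete, testable pipeline for the
standard strategy: expand each index SNP to its correlated surrogates, ask
in which cell types those risk SNPs pile up inside active regulatory
chromatin more often than chance, and then follow up the enriched loci with
allele-specific motif scoring and eQTL links.

## The model, stage by stage

### LD expansion

Risk SNPs are defined as the index SNP plus every variant within a window
of total span `window_bp` (default 1 Mb, read as ±500 kb around the index;
the span is configurable for a ±1 Mb reading) whose squared correlation
with the index across phased haplotypes reaches `r2_min = 0.8`:

$$ r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad D = p_{AB} - p_A p_B $$

with \(p_A, p_B\) the alternate-allele frequencies and \(p_{AB}\) the joint
haplotype frequency. This is algebraically the squared Pearson correlation
of the two binary allele vectors, which is the oracle the test suite checks
against. We compute \(r^2\) from phased haplotypes only; unphased input is
rejected rather than approximated by genotype-dosage correlation, because
the two disagree under departures from Hardy–Weinberg and the contract is
haplotype LD. Index SNPs can be removed up front via an exclusion list
(e.g. assembly exceptions), and loci whose risk set collapses to the index
alone are skipped with a log line.

### Rules-based segmentation

Each cell type's genome is classified from three histone-mark peak sets,
in decreasing precedence:

* H3K4me3 peaks are **promoters**: `PAR` (active) if the peak overlaps any
  H3K27ac interval by at least 1 bp, else `PPR` (poised).
* Bases covered by H3K4me1 but not by any H3K4me3 peak are **enhancers**:
  `EAR` if the containing merged H3K4me1 peak overlaps H3K27ac, else `EPR`.
* Everything else is unlabelled (`NONE`).

Two resolution choices were genuinely open. Activity is decided at the
*peak* level — one base of H3K27ac overlap activates the whole peak —
because overlap-fraction thresholds would introduce an unstated parameter.
Promoter precedence, by contrast, is resolved *base-wise* where the two
methylation marks overlap, so that every marked base receives exactly one
label and the labelled bases partition exactly the H3K4me1 ∪ H3K4me3
footprint. Both properties are fuzz-tested. Coordinates are BED-style
0-based half-open internally at the interface, with SNP positions converted
from 1-based VCF convention.

Four non-`NONE` states are exposed. We deliberately do not collapse them
into a three-way grouping: the combination rules admit four informative
states plus background, and any grouping can be applied downstream.

### Hypergeometric enrichment

For one locus, one cell type and one state category, let \(N\) be the
background SNPs in the window, \(K\) of them in the category, \(n\) the
risk SNPs and \(k\) the risk SNPs in the category. The enrichment p-value
is the upper tail \(P(X \ge k)\) for
\(X \sim \mathrm{Hypergeometric}(N, K, n)\), summed in log space. The
background *includes* the risk SNPs (they are window SNPs drawn without
replacement), no MAF filter is applied, and the pooled category `EAR&PAR`
counts a SNP once if it is in either active state.

The multiple-testing family is a real ambiguity: corrections could be
locus-specific or per cell type. Both are implemented behind
`fdr_family = c("locus", "cell_type")`; the default adjusts all cell types
× categories within one locus (Benjamini–Hochberg, q < 0.05), which
matches a locus-specific reading. The enrichment matrix holds
\(-\ln q\) by default (`neg_ln_p` is available), with absent tests stored
as 0.

### Clustering and heatmap

Cell types and loci are clustered by average-linkage (UPGMA) on Euclidean
distances between the \(-\ln q\) vectors; the heatmap orders both axes by
dendrogram leaf order with a white→red ramp. UPGMA and distances are
delegated to `stats::hclust`/`stats::dist` and verified against a naive
\(O(n^3)\) agglomeration oracle in the tests; dendrograms export as
Newick.

### Allele-aware motif disruption

For a SNP in regulatory chromatin, every PWM window overlapping the SNP on
both strands is scored for the reference and alternate alleles with the
weighted sum \(\sum_j \log(p_{j,b_j}/\pi_{b_j})\) (background \(\pi\)
uniform by default), min–max scaled to [0, 1] so the consensus scores 1.
The match p-value — the probability that a random background sequence
scores at least as high — is computed exactly up to discretisation by
dynamic programming over the per-position score distribution, with bin
width \(10^{-3}\) of the raw-score range; the resulting error is orders of
magnitude below the 5×10⁻⁵ reporting cutoff, and the DP is checked against
exhaustive \(4^w\) enumeration for small widths. Per (SNP, motif) the best
window/strand by minimum p is reported when that minimum reaches the
cutoff; a stricter 10⁻⁵ threshold is carried separately for plotting-grade
calls. The scaled score difference (alt − ref) gives the direction
(negative = site destroyed) and an `effect` grade (strong/weak at an
invented, configurable threshold of 0.4). This module defines its own
weighted-sum contract rather than reproducing any existing scanner's
internals; results may diverge from other tools in tie cases.

### eQTL linking

Association records are subset to the LD-expanded risk-SNP set at
p ≤ 2.5×10⁻⁵ and joined to the enrichment calls through a user-supplied
cell-type ↔ eQTL-tissue map (the two ontologies overlap only partially and
no canonical mapping exists, so it is an explicit input, never guessed).
A pre-filter at p ≤ 0.05 on the input table is available; effect direction
is carried as a sign only. The concordance table reports, per (locus,
mapped tissue), whether the locus is enriched at q < 0.05 and how many
distinct genes have significant eQTL support.

## The synthetic study

Real inputs at consortium scale (reference haplotype panels, dozens of
cell types' peak calls, full eQTL tables) are neither shippable nor needed
to validate the machinery, so the package generates a desk-scale study
with known planted truth. The default configuration is the reference
condition used throughout the tests and the acceptance script:

* 8 loci × 10 cell types; each locus on its own chromosome with the index
  SNP at the centre of a 1 Mb window;
* 400 haplotypes; 15 risk SNPs per locus with target r² drawn from
  [0.85, 0.98] (planted by conditional sampling from the 4-cell haplotype
  distribution, feasibility checked against the Fréchet bounds);
  ~200 background SNPs per window (density 2×10⁻⁴/bp), uniform positions,
  frequencies uniform in [0.1, 0.9];
* fixed-width 1 kb peaks; active-enhancer coverage 10% of the window
  (the background category rate), 30 poised-enhancer and 20 promoter peaks
  per window; one planted (locus 1, tissue 1) pair where peaks are placed
  over 80% of the risk SNPs;
* a 6 kb motif contig with three sharply informative synthetic PWMs
  embedded at consensus, with one middle-of-motif SNP each (two destroy a
  site, one creates it);
* an eQTL table with two planted significant records per planted pair,
  plus noise and significant decoy records on non-risk SNPs.

Haplotype counts, densities and peak geometry were chosen once as
desk-scale-realistic; empirical r² of a planted pair concentrates within
±0.05 of target at 2,000 haplotypes, and at 400 haplotypes an occasional
surrogate drops below the 0.8 threshold, which the truth bookkeeping
records rather than hides. What the generator deliberately does **not**
emulate: recombination-map LD block structure (LD is planted pairwise
against the index only), realistic allele-frequency spectra, variable peak
widths, chromatin-domain correlation between cell types, and motif
instances inside the locus windows. Passing recovery tests therefore shows
the *machinery* is correct and calibrated, not that real data meet the
generator's assumptions.

All randomness derives from one master seed through fixed per-component
streams, so every emitted file is byte-identical across reruns and partial
regeneration is stable.

## Numerical and degenerate-input choices

* Hypergeometric tails are log-sum-exp sums of `lchoose` terms; the tests
  require agreement with exact enumeration to 10⁻¹⁰ relative error over
  all parameter combinations with N ≤ 60.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` and is
  checked against an independent hand-written step-up.
* Monomorphic variants have undefined LD: `compute_r2` errors, and the
  vectorised window scan returns `NA` for such columns so callers skip
  them.
* UPGMA ties are resolved by `stats::hclust`'s deterministic ordering;
  reruns give identical trees.
* Motif windows containing non-ACGT bases are skipped with a message; a
  reference-allele mismatch against the genome is a hard data-integrity
  error.
* Single-row or single-column matrices degrade gracefully (warning, no
  clustering of that axis).

## Problem sizes used in validation

The shipped validation runs at the default scenario size (8 × 10, ~1,700
SNPs): 50 planted-recovery seeds and 200 all-null seeds for the
enrichment operating characteristics, 1,000 fuzzed peak configurations for
the segmentation invariants, 1,000 random vector pairs for the LD and BH
oracles, exhaustive enumeration up to width-8 PWMs, and full
hypergeometric enumeration to N = 60. These sizes make the whole
validation reproducible on a laptop in minutes while keeping the binomial
error of the recovery-rate estimates small relative to the thresholds
being tested.

## Known limitations

* The three-histone-mark rule set cannot call silenced, heterochromatic or
  transcribed states; marks for those are out of scope.
* The FDR family the original analysis used is not recoverable from
  published descriptions; both implemented readings are exposed and the
  default is documented above.
* Enrichment treats SNPs as exchangeable within the window; LD-aware
  effective-number-of-tests corrections and permutation nulls are not
  implemented.
* The motif stage handles biallelic single-base substitutions only (no
  indels, no dinucleotide background).
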