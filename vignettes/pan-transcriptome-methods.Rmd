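---
title: "Methods: polyploid pan-transcriptome analysis with pantriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyploid pan-transcriptome analysis with pantriad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantriad)
```

`pantriad` implements the downstream computations of a multi-cultivar,
multi-tissue transcriptome survey of a polyploid crop: each cultivar has
its own assembly, annotation and count matrix, orthology links the gene
sets, and the questions are about conservation and divergence of the
gene repertoire and its expression. This vignette documents the models,
the parameters that matter, the synthetic data used to validate them,
and the design decisions taken where more than one reading was
defensible.

## Count normalization

All expression statistics run on median-of-ratios normalized counts.
For genes with positive counts in every sample of a cultivar, the
reference is the gene's geometric mean across that cultivar's samples,
and a sample's size factor is the median of its count/reference ratios;
normalized counts are raw counts divided by the factor. Normalization is
**per cultivar** (`normalize_bundle()`): each cultivar's libraries were
aligned to its own assembly, so cross-cultivar columns share no
meaningful per-gene reference. Genes with any zero count are excluded
from the median, and a cultivar in which no gene is positive everywhere
is an error rather than a silent fallback. `size_factors()` is checked
in the test suite against DESeq2's `estimateSizeFactorsForMatrix()`.

Assumption: counts are overdispersed relative to Poisson, with a roughly
shared composition across samples so that a single per-sample scalar
captures library depth. Differential-expression inference (dispersion
shrinkage, Wald/LRT tests) is out of scope.

## Homoeolog bias: triads, centroids, stability

A triad is one gene per subgenome (A, B, D) of one cultivar; an *n*-let
is an orthogroup forming a strict 1:1:1 triad in *every* cultivar
(`build_nlets()` rejects any orthogroup with a missing or duplicated
member). Relative expression is the triad's share vector
(r_A, r_B, r_D) of mean normalized expression, by default averaged over
all conditions; a per-tissue mode is available through the `tissues`
argument of `nlet_bias()`. The category is the nearest of seven fixed
centroids (Balanced, three dominant, three suppressed) in Euclidean
distance, the scheme established for wheat triads; the centroids are
exposed by `bias_centroids()` and can be overridden. Decisions here:

* **Not-expressed cutoff.** A triad with total mean normalized
  expression below 0.5 is NotExpressed rather than force-classified.
  All-zero triads are flagged, not dropped, so partitions stay
  exhaustive.
* **Ties.** Exact distance ties are measure-zero; they break by the
  fixed order Balanced < dominants < suppressed, which keeps the
  classifier deterministic.
* **Stability.** An n-let whose category agrees in every cultivar is
  stable (balanced/dominant/suppressed by the shared category);
  NotExpressed everywhere is its own class; *any* other disagreement is
  dynamic. The partition is exhaustive and exclusive by construction and
  the test suite asserts both on synthetic data and on the published
  count arithmetic (8,028 + 5,052 + 276 + 63 + 102 = 13,521).

## Tissue specificity

tau = Σ(1 − x_i)/(N − 1), x_i the per-condition expression normalized by
the gene's maximum; 1 means single-condition expression, 0 a flat
profile. Conditions are replicate means per (cultivar, tissue) — the
per-condition wording of the index — computed over the four
developmental tissues (flag leaf, root, spike, grain) by default;
the circadian dawn/dusk samples can be added via `tissues=`. Genes with
tau at or above 0.8 are assigned to the tissue of their maximal mean.
An all-zero profile has no defined tau and returns `NA`.

## Tandem arrays and chains

Arrays are maximal runs of same-family (orthogroup) genes in chromosome
gene order, allowing up to `max_gap` intervening other-family genes.
`max_gap` defaults to 1, the common collinearity-scanner tolerance; the
value is configurable and recorded in the pipeline manifest since the
choice is not dictated by the balance cutoff. Exactly two copies is a
TrueTandem, more a TandemArray. Balance: an array is unbalanced when one
member carries ≥ 0.8 of the array's total mean normalized expression or
when it is the only expressed member; the same maximal-share rule covers
arrays larger than two. Arrays with no expressed member are flagged
not-expressed and excluded from balance counts. Chains link arrays of
the same family across ≥ 2 cultivars (largest array per cultivar,
leftmost on ties) and are *constant* when all member arrays share one
balance label. Note that for published TrueTandem balance figures the
counts and the percentages quoted alongside them are mutually
inconsistent (2,384/534 of 2,918 is 81.7%/18.3%); `pantriad` reports
counts and percentages derived from them only.

## k-mer coverage and introgression candidates

The coverage score of a gene against another genome is the fraction of
its overlapping k-mers (k = 51 by default; odd k required) present
anywhere in that genome. Decisions:

* **Canonical k-mers.** Queries and the index are strand-agnostic
  (lexicographic minimum of forward and reverse complement): assemblies
  differ in orientation, so strand-blind matching is the safe reading.
  Scores are invariant under reverse-complementing the target (tested).
* **Exact membership.** The index stores 2-bit-packed k-mers in a
  sorted vector queried by binary search — no false positives, ~16
  bytes per k-mer. k-mers containing non-ACGT characters are excluded
  on both sides.
* **Gene sequence.** The unspliced genomic span of the gene model is
  scored ("genic regions"); a CDS-based scan is a caller-side choice of
  input sequences.
* **Set fraction.** The score is the fraction of k-mers present, the
  plain reading of a 0–1 "coverage score"; positional run statistics
  are not used.

Windowed tracks average gene scores (genes placed by midpoint) over
sliding windows, 2 Mb / 5 kb by default. Candidate intervals are maximal
runs of windows below a mean-score threshold (default 0.5, matching the
expected intact-k-mer fraction (1 − d)^k ≈ 0.36 at 2% divergence, which
sits clearly below it while undiverged windows sit at ~1) containing at
least `min_genes` scored genes. The threshold is a calling convenience —
the track itself is the primary output.

## Epitope motifs and expression scores

Peptides are reverse-translated with the standard nuclear codon table:
each residue's codons are merged positionwise into minimal IUPAC codes,
so "F" becomes TTY. A scan position matches when every genome base is a
member of the motif's IUPAC class; the genome side must be concrete —
`N` matches nothing, which is the conservative reading of "100% sequence
identity". Scans run on the annotated sense strand by default with a
`search_revcomp` switch. Scores multiply a gene's normalized expression
by its occurrence count and sum per epitope group and (group, subgenome);
the score is linear in expression by construction. Co-expression edges
use Pearson r on log2-transformed normalized counts (values ≤ 1 masked
before the log), two-sided t-based p values, BH adjustment across all
tested pairs, and the r > 0.8, adjusted p < 0.01 filter.

## Module eigengenes, divergence, metamodules

Module construction itself (soft thresholding, topological overlap) is
out of scope: assignments are inputs, from files or from the generator.
An eigengene is the first right singular vector of the module's
standardized (per-gene z-scored) expression, unit-norm over samples and
sign-oriented to correlate positively with its members on average; the
variance explained is reported. Module distance is d = 1 − Pearson r of
eigengenes — the standard reading of correlation-based dissimilarity.
The divergence threshold is `fraction` (default 0.85) times the median
of per-module maximum distances, computed **per cultivar network**
("for each cultivar …"); triads whose homoeologs span modules are
*similar* when all pairwise module distances stay at or below the
threshold and *divergent* otherwise. Metamodules pool all cultivars'
eigengenes (columns condition-matched), cluster 1 − r by
complete-linkage `hclust`, and pick k over 2..10 by mean silhouette
width with the Dunn index breaking ties — fixed this way because both
indices are reported as agreeing in the motivating analysis. Both
indices are implemented from their definitions (no suitable package
ships the Dunn index here) and are tested against brute-force loops and
`cluster::silhouette`.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions:

* 10 cultivars × 3 subgenomes, one chromosome per subgenome, genes laid
  out in orthogroup order (300 bp genes, 700 bp spacing — compact but
  preserving order and windowing behaviour).
* Orthogroup classes drawn at the published average proportions
  (62.5/36.6/0.9%); shell cardinalities uniform on 2..n−1 with optional
  "breeding-block" correlation to emulate programme-specific sharing.
* Negative-binomial counts, var = μ + φμ², over 6 tissues × 3
  replicates; φ defaults to 0.05, a typical gene-level RNA-seq
  overdispersion. Per-sample size factors are log-uniform on
  [0.7, 1.4]; per-tissue effects are log-normal with a 2× spread (one
  sd spans a twofold change), applied to the whole triad so bias is
  preserved across tissues — no per-tissue effect sizes being
  available, this is the one free choice, made once.
* Planted stability labels at the published 30-let partition
  proportions (59.4/37.4/2.0/0.45/0.75%). Stable n-lets sit exactly on
  a centroid; dynamic n-lets are blended 20% of the way toward a random
  simplex point, and their truth category is re-derived as the nearest
  centroid of the blended point. The blend reproduces the observed
  pattern that dynamic triads lie further from the centroids than
  stable ones while keeping the truth category the exact noiseless
  classification; without it the truth would be degenerate (all points
  on centroids) and that property untestable.
* Tandem arrays are planted as adjacent extra copies with balanced
  (equal means) or unbalanced (95/5) expression and a planted
  constant-chain fraction of 0.53, the published split.
* Genomes share one ancestral sequence per orthogroup slot across
  cultivars (so cross-genome coverage is exactly 1 before divergence is
  planted) and have independent random intergenic sequence; there is no
  sequence-level homology *between* orthogroups. Introgressions are
  i.i.d. substitutions at a given rate inside an interval.
* Module structure is latent-factor: orthonormal factor profiles over
  samples, positive loadings, Gaussian noise; 4 networks × 17 modules
  over 6 factors gives the 68-eigengene setting.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequence homology within orthogroups,
splice isoforms, transposon landscapes, mapping ambiguity between
near-identical duplicates, batch structure beyond scalar size factors,
and biologically correlated (rather than planted) bias categories.
Recovery rates on synthetic data are upper bounds for real data, where
quantification error and annotation noise add on top.

## Problem sizes, determinism, degenerate inputs

The test suite and the acceptance script use 1,000 n-lets × 9 cultivars
at φ = 0.05 for bias recovery (≥ 95% per cultivar observed ~99.5%;
stable/dynamic ≥ 98% observed ~100%), 10⁴ orthogroups for class
proportions (±1%), a 13 Mb chromosome with a 5 Mb block at 2% divergence
for the introgression scan (interval Jaccard ~0.85), and 68 eigengenes
with 6 planted factors for metamodule selection — sizes chosen to make
the statistical checks sharp while a full run stays around a minute.
All randomness flows from a single integer seed through per-stage
derived seeds; identical (bundle, config, seed) inputs produce
byte-identical pipeline outputs, which the suite asserts.

Degenerate inputs are handled explicitly rather than by NaN
propagation: all-zero tau profiles return `NA`; all-zero triads are
flagged not-expressed; constant genes are dropped from eigengenes with
a warning (all-constant is an error); constant expression profiles are
skipped by the co-expression scan with a warning; near-identical
eigengenes degrade metamodule selection to the minimum k with a
warning.

## Coordinate conventions

Gene tables use 1-based inclusive coordinates throughout — the native
convention of GFF3 and of R/Bioconductor ranges, which every function
here consumes and produces. BED files are 0-based half-open on disk;
`read_bed()`/`write_bed()` convert at the boundary (via rtracklayer), so
no arithmetic inside the package ever mixes conventions.

## Known limitations

Orthology inference, annotation, alignment and module detection are
consumed, not performed. The Fisher enrichment treats genes as
exchangeable units (no length or density correction). Dunn's post-hoc
test uses the large-sample normal approximation, not permutation. The
epitope scan does not align — insertions or sequencing gaps in a motif
occurrence are missed by design under exact matching.
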