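---
title: "Methods: quantifying feeder-cell contamination in stem cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying feeder-cell contamination in stem cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feederscan)
```

## The problem

Human pluripotent stem cells (hPSCs) are classically co-cultured on
mitotically inactivated mouse embryonic fibroblasts (MEF "feeder" cells).
Isolation of the human cells before sequencing is never perfect, so hPSC
mRNA-Seq and small RNA-Seq libraries routinely contain mouse-derived
reads. Standard pipelines align reads to the human genome only; mouse
reads that happen to align to similar human loci then inflate the apparent
expression of those human genes and miRNAs. feederscan implements two
complementary analytics:

1. **Species partitioning for mRNA-Seq.** Reads are aligned to both
   genomes; a read is called *human-specific* when it maps uniquely to the
   human genome and not at all to the mouse genome (and symmetrically).
   Any read mapped in both genomes is discarded as ambiguous. The
   *mixing ratio* is

   $$\hat\varphi = \frac{n_{\text{mouse-specific}}}
   {n_{\text{mouse-specific}} + n_{\text{human-specific}}},$$

   with ambiguous and unmapped reads excluded from both numerator and
   denominator.

2. **Cross-species miRNA clustering and cluster-level quantification.**
   Mature miRNAs of both species are mapped to both genomes under two
   regimes — edit distance at most 2 (substitutions and gaps), and at most
   3 substitutions gap-free — and the hit sets are merged. miRNAs whose
   loci overlap by more than 90% of the shorter interval are merged into
   clusters (single linkage). A cluster with annotated members of both
   species is **Conserved**; a single-species cluster whose sequences
   align to the other genome (but overlap no annotated miRNA there) is
   **Type-B**; one with no qualifying alignment to the other genome at all
   is **Type-A**. Clusters, not individual miRNAs, are the quantification
   unit, which sidesteps read misassignment among near-identical isomiR
   family members. Cluster names follow the
   `<mouse members>__<human members>` convention with `NA` for an empty
   side (e.g. `mmu-miR-a__NA`).

Type-A miRNAs cannot be produced by reads of the other species, so a
single read on a mouse Type-A marker is species-proof evidence of feeder
residue. Type-B and Conserved markers are called by expression pattern:
more than 10 RPM in feeder cells and less than 1 RPM in feeder-free hESC
samples (Type-A markers need only exceed 1 RPM in feeder cells).
Misalignment-prone features are flagged by fold-change rules: human genes
whose apparent expression from MEF reads mapped to the human genome is at
least 2-fold their expression in clean hESCs, and conserved miRNA
clusters with at least a 10-fold feeder/feeder-free increase.

## The built-in mapper

Real-scale runs ingest SAM/BAM from an external aligner via `load_sam()`.
For desk-scale work and for all validation, `map_queries()` provides an
exhaustive mapper with exact semantics:

* **mismatch mode**: fixed-length windows, substitution count ≤ k;
* **diff mode**: unit-cost edit distance ≤ k (substitutions + indels).

One hit is reported per qualifying window start; in diff mode the
reported end is the smallest end achieving the minimal distance for that
start. This "one hit per start" definition makes the hit set well defined
and directly checkable against a position-wise dynamic-programming scan.
A consequence is that a single genomic placement yields a small cloud of
hits at neighbouring starts (within k); `hits_to_align_summary()`
therefore collapses overlapping same-strand hits into placements before
uniqueness is judged, mirroring how a production aligner reports one
alignment per locus.

Candidate generation uses exact pigeonhole seeding: a query with at most
k differences is split into k+1 pieces, at least one of which must match
the genome exactly, so seeding is lossless — no qualifying hit can be
missed. `N` never matches anything, on either side; this is conservative
and prevents N-runs from generating spurious species-specific calls.
Coordinates are 0-based half-open everywhere internally; BED export is
native, SAM import is converted.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_diff` | 2 | edit-distance cap, gapped regime (annotation) |
| `max_mismatch` | 3 | substitution cap, gap-free regime (annotation) |
| read-mapping k | 2 | edit-distance cap for quantification reads |
| `min_overlap` | 0.9 | locus/read overlap threshold (strict `>`) |
| marker feeder RPM | 10 | Type-B/Conserved markers: feeder floor (strict `>`) |
| marker clean RPM | 1 | Type-B/Conserved markers: hESC ceiling (strict `<`) |
| Type-A marker RPM | 1 | Type-A markers: feeder floor (strict `>`) |
| marker-gene fold | 20 | cell-type markers, strict `>` over every other type |
| influenced-gene fold | 2 | "at least" rule, `>=` |
| influenced-miRNA fold | 10 | conserved clusters, `>=` |
| pseudocount `eps` | 0.1 RPM/FPKM | all fold rules; guards zero denominators |
| FPKM expression floor | 1 | inclusive, in at least one sample |
| MAPQ floor (`load_sam`) | 1 | part of the uniqueness policy |

Strictness mirrors each rule's wording: "more than" thresholds are
strict, "at least"/"no less than" thresholds are inclusive.

## Design decisions

* **Uniqueness for SAM input** is operationalized as: exactly one
  alignment record (no secondary/supplementary) with MAPQ at or above the
  floor. This is the standard reading of "uniquely mapped".
* **Reads mapped in both genomes are ambiguous even when unique in only
  one** — mutual exclusivity is what makes the mixing ratio a
  species-origin estimate. Reads multi-mapped in exactly one genome are
  also labelled ambiguous (they are neither confidently specific nor
  bilaterally mapped); the four labels partition the read universe.
* **Overlap denominator** is the shorter interval, so a short isomiR
  fully inside a longer locus counts as complete overlap; a
  reciprocal-overlap variant is available via the `denominator` argument.
* **Single-linkage merging**: transitive chains (A overlaps B, B overlaps
  C) form one cluster, which is what cluster naming like `miR-A/B/C`
  implies. Within-genome and cross-genome overlaps are resolved in one
  graph; under single linkage, merging them in either order gives the
  same components.
* **One mappable member suffices**: a mouse-only cluster counts as Type-B
  if the union of its members' loci touches the human genome.
* **Multi-cluster reads** are assigned to the cluster with the largest
  overlap fraction; exact ties are left unassigned and logged. This keeps
  each read counted at most once and the per-sample count total bounded
  by the mapped-read denominator.
* **RPM denominators.** RPM is computed per sample as
  count × 10⁶ / mapped reads of that sample (reads with at least one
  genome hit after QC). A published description of this normalization
  reads "using the total number of samples", which we take to be a slip
  for the sample's total mapped reads — the only reading under which RPM
  has its standard meaning. An `assigned_reads` denominator policy is
  available; it rescales every cluster by a constant per-sample factor.
* **Replicate aggregation** for threshold rules is the mean across a
  condition's samples by default (`max`/`min` give stricter variants).
* **Fragments vs reads**: counts are per read; the simulator and the
  desk-scale pipeline are single-end throughout.
* **Mismatch sweep** (`sweep_typeA_counts()`) re-runs the gap-free regime
  at k = 0..3 and reclassifies, reproducing the strong dependence of the
  Type-A census on the allowed-difference setting.
* **Cell-type marker genes** require the fold-change to hold against
  *every* other cell type column, matching the "compared to hepatocyte
  and MEF samples" construction.

## The synthetic data generator

`generate_genomes_and_annotation()` builds two uniform-random genomes
(default 200 kb each) — random backgrounds are effectively fully
divergent, so cross-species read specificity holds by construction away
from planted loci. Into them it plants, by default, 10 conserved miRNA
pairs (copies separated by a configurable number of substitutions,
default 1), 5 Type-A and 5 Type-B loci per species, and annotates 20
non-overlapping multi-exon genes per species in a disjoint genome region.
Type-A status is *verified*, not assumed: each Type-A sequence is mapped
against the final other-species genome under both regimes and regenerated
on any hit. Per-locus abundances are log-uniform on [1, 100] and drawn
once per fixture, so feeder, clean and query samples simulated from one
fixture share an expression profile.

Read simulation draws each read's species Bernoulli(φ), a source locus
from the species' abundance vector, applies 0–2 nt of random 3' trimming
to small reads (so the >90% read-overlap rule is genuinely exercised by
isomiR-like length variants), injects substitution errors at the
configured rate (default 0.5%), and optionally appends adapters. Every
read carries a ground-truth record.

What the generator does **not** emulate: transcript splicing across
exon junctions, expression dynamics, quality-score-correlated errors,
indel sequencing errors, ligation and PCR biases of small-RNA library
construction, paired-end fragments, and the repeat structure of real
mammalian genomes. Passing tests on synthetic data therefore validate
the *algorithmic* pipeline — exhaustive mapping, partition logic,
clustering, threshold rules, normalization — under known truth; they do
not by themselves calibrate real-data error rates, where misalignment is
driven by genuine homology rather than planted divergence.

## Numerical choices and degenerate inputs

* Fold rules add `eps = 0.1` to numerator and denominator, so a feature
  absent from the clean sample yields a large finite fold rather than a
  division by zero.
* A mixing ratio with zero species-specific reads in both genomes is an
  error (undefined), deliberately distinct from the value 0.
* Median of an even-sized group is the mean of the central pair.
* Tie-breaks: equal-overlap cluster assignment → unassigned; equal
  `n_diff` across the two mapping regimes for the same placement → the
  gapped-regime record is kept.
* Empty member sides print as `NA` in cluster names; clusters are ordered
  and numbered (`cl0001`, ...) by sorted canonical name, so cluster ids
  are stable across runs and input orderings.
* Byte-identical reproducibility under a fixed seed is part of the
  generator's contract and is tested.

## Validation scales

The automated suite validates, among other properties: equality of the
mapper with an independent vectorised DP oracle on 100 random instances
(genomes up to 20 kb); mixing-ratio recovery at φ ∈ {0.001, 0.01, 0.05,
0.2} with 50,000 reads × 10 seeds (relative error of the mean estimate
below 10%, and exactly zero mouse-specific reads at φ = 0 with error-free
reads); exact recovery of every planted cluster type on the default
fixture; the planted Type-A census at each allowed-mismatch value 0–3;
threshold rules against brute-force filters; and end-to-end
specificity/sensitivity on mixtures at φ ∈ {0, 0.01, 0.1} (3,000 reads ×
5 seeds). These problem sizes keep the whole suite to a few minutes on a
single core while leaving the binomial/multinomial sampling noise well
below the tested tolerances.

## Limitations

* The built-in mapper is exhaustive and exact but desk-scale; whole-genome
  runs should use a production aligner and `load_sam()`.
* Some real Type-B miRNAs overlap other small-RNA loci (rRNA, snRNA,
  snoRNA), which can blur their feeder specificity; no filter for such
  overlaps is implemented.
* Differential-expression testing, transcript assembly, spliced
  alignment, isomiR end-variant cataloguing and UMI handling are out of
  scope.
* Figure rendering (heatmaps, PCA, circos) is out of scope; the package
  exports plain matrices (e.g. `expr_correlation()`) for downstream
  plotting.
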