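---
title: "Methods: phased copy-number evolution from sparse single-cell WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phased copy-number evolution from sparse single-cell WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaphase)
```

# The model

`cnaphase` analyses tumour genome evolution as an ordered sequence of
copy-number phases following loss of the p53 tumour suppressor:

1. **LOH** — a founding hemizygous deletion on the chromosome carrying the
   p53 locus removes the remaining wild-type allele.  Independent founder
   lineages carry deletions with distinct breakpoints, all spanning the
   locus.
2. **Deletion accumulation** — while still diploid, each lineage
   accumulates further hemizygous deletions; gains are essentially absent
   in this phase.
3. **Whole-genome doubling (WGD)** — a rearranged diploid genome doubles,
   producing a tetraploid carrying every earlier deletion at twice the
   copy number.
4. **Gains and amplifications** — broad single-copy gains and focal
   high-level amplifications emerge only after doubling, diversifying the
   doubled population into subclonal branches.  Single-copy losses continue
   in this phase; it is the *onset of gains* that is phase-gated.

The measurement model is sparse whole-genome sequencing of single cells:
reads are counted in ~600-kb genomic bins (5,000 bins for a mouse-sized
genome, 20,000 for human), with on the order of $10^6$ reads per cell.

# Synthetic data generator

`sim_config()` / `simulate_lineages()` / `profiles_to_counts()` emit
ground-truth lineages following the four phases plus noisy counts.

Key defaults and their reasoning (the reference study conditions):

* `n_bins = 5000`, bins apportioned over packaged mm9 chromosome lengths;
  `reads_per_cell_mean = 1e6`; QC floor 250,000 reads.
* `dispersion = 0.085`: gamma–Poisson (negative binomial) bin counts with
  $\mathrm{Var} = \mu + 0.085\,\mu^2$, giving a per-bin coefficient of
  variation of ≈0.3 at 200 reads/bin — the quality regime of usable sparse
  single-cell WGS.
* GC bias: a quadratic response in bin GC fraction centred at GC 0.45,
  scaled by `gc_bias_strength` (default 0.2), floored at 0.05.
* `n_loh_lineages = 3` independent founders; founder LOH boundaries drawn
  uniformly, constrained to span the p53-locus bin, and kept distinct
  across founders (they model *competing* lineages).
* `deletions_per_phase = 3`, `gains_post_wgd_rate = 3`,
  `focal_amp_rate = 1`: the per-phase event rates are not quantified by the
  underlying biology at bin resolution, so these are order-of-magnitude
  choices exposed in the configuration rather than calibrated constants.
* Event sizes: deletions log-uniform from 5 bins to a whole chromosome;
  focal amplifications span 1–5 bins at state ≥ 8.  This spans both the
  "recurrent broad deletion" and the "single focal driver" regimes.
* `wgd_probability = 0.33` per founder; `polyploid_fraction_target = 0.15`
  of the rearranged population (the 10–20% range observed for polyploid
  pre-tumour cells); each doubling spawns `n_wgd_branches = 3` sublineages
  with private post-doubling events, so doubled deletions are clonal
  within the doubled population while gains are subclonal.
* Each doubled branch acquires at least one gain: phase 4 is *defined* by
  the emergence of gains, and a doubled genome carrying only even states is
  quantally indistinguishable from its diploid half at sparse coverage.
* Cells are assigned to leaf lineages (the expanded clones); founder LOH
  states are recorded as ancestral nodes without sampled cells.
* Randomness: one root seed; every cell draws a private stream through a
  stable string hash (`derive_seed`), so adding cells never perturbs
  existing ones, and the whole bundle is reproducible bit-for-bit.

What the generator does *not* emulate: amplification-free WGA artefacts
with genomic waviness, mappability structure (bins are equal-length, not
mappability-scaled), chromothripsis, SNVs/haplotypes, and doublets.
Passing recovery tests on these simulations therefore demonstrates the
pipeline's statistical behaviour under controlled noise, not performance
on any particular real library chemistry.

# Copy-number calling

Per cell, `call_cells()` chains four steps.

**QC** (`qc_filter`): cells under 250,000 total reads are excluded; the
boundary is inclusive.

**GC correction** (`gc_correct`): LOWESS of count vs GC fraction
(span 0.3), corrected value = count / fitted, rescaled to mean exactly 1.
The fit is two-pass: copy-number structure confounds a single fit wherever
an altered region dominates its own GC stratum, so the curve is re-fitted
using only bins whose first-pass ratio lies within ±20% of the modal
level (when at least 20% of bins qualify).  Fitted values are floored at
$10^{-6}$ × mean count.

**Segmentation** (`segment_profile`): circular binary segmentation.
Within each chromosome the arc maximising the circular mean-shift
statistic $|D|/\sqrt{m(n-m)}$ is tested against a within-chromosome
permutation null at `alpha = 0.01` (1,000 permutations, with early
stopping once significance is impossible), and accepted splits recurse.
Numerical choices that matter:

* Change points are *located* on an outlier-smoothed (running median,
  4 robust-SD winsorisation) log ratio.  The log transform stabilises the
  multiplicative noise so deletions test at full contrast; the smoothing
  prevents 1–2-bin amplification spikes from dominating both the observed
  maximum and its permutation null (which would otherwise leave whole
  chromosomes unsegmented).
* Accepted cuts are then refined on the *unsmoothed* log ratio (±8 bins,
  two passes, least squares), because the running median smears step
  edges by a few bins.
* Segment means and within-segment variances are computed from the raw
  (linear) ratios; segments shorter than `min_seg_bins = 3` are merged
  into the nearer-mean neighbour.

**Quantal ploidy fit** (`fit_ploidy`): a multiplier $q$ on the grid
1.5–6.0 (step 0.05) maps ratios to absolute copies.  `fit_error` is the
classical objective $\sum_i (q\,\bar r_i - \mathrm{round}(q\,\bar r_i))^2$
over bins.  Scale *selection*, however, cannot use that objective alone:
each segment's sampling deviation enters the residual scaled by $q^2$, so
the raw sum is systematically biased toward the halved, quantally
degenerate scale of an even-ploidy genome.  Selection therefore compares
scales by precision-weighted least squares of the segment means against
the lattice $c/q$ (weights $n_j/s_j^2$, with per-segment variances shrunk
toward the pooled coefficient of variation, prior df 10), and takes the
smallest $q$ within $1.5\times$ the minimum plus one chi-square standard
error ($\sqrt{2\,\#\mathrm{segments}}$).  The band absorbs the bounded
overfitting gain of denser harmonic lattices; exact ties (a no-odd-state
genome fits 2n and 4n identically) resolve to the lower scale, while a
single sizeable odd-state segment rejects the halved scale decisively.
Cells with fitted mean ploidy ≥ 3.0 are labelled polyploid.

# Clonal inference

`extract_breakpoints()` marks boundary $b$ for a cell when the absolute
state change across it is ≥ `min_delta = 1`; chromosome-terminal
junctions are never eligible.  Boundaries within ±1 bin across cells are
union-merged to a canonical (leftmost) representative, and the Fisher
universe $N$ is the eligible-boundary count reduced by that merging.

Pairwise dissimilarity is the one-sided Fisher exact p-value (upper
hypergeometric tail) for enrichment of shared canonical breakpoints; a
breakpoint-free cell carries no evidence and scores 1.  Trees use average
linkage on the dissimilarity matrix with cells pre-sorted by id, so the
result is invariant to input order.

The permutation null redistributes the pooled multiset of observed
breakpoints among cells, preserving each cell's count exactly (duplicate
assignments are resolved by swaps so row sums and the pooled multiset are
both conserved), and recomputes all pairwise dissimilarities
(`n_perm = 500`).

A node at height $h$ receives
$$\widehat{\mathrm{FDR}}(h) = \frac{\text{mean null pairs} \le h \text{ per
permutation (all pairs)}}{\#\{\text{within-node pairs} \le h\}},$$
clipped to $[0,1]$; nodes with FDR ≤ `t = 0.01` are accepted and clones
are the maximal accepted nodes.  Counting the null over *all* pairs gives
the estimator its multiplicity control: an isolated lucky pair is expected
about once per permutation and scores FDR ≈ 1, while the many coincident
pairs of a real clone are never reproduced by the null.  Node heights are
widened by a relative $10^{-9}$ when counting, because average-linkage
heights coincide with pair values up to floating error.

`trace_wgd_precursors()` links each polyploid cell to the diploid cell
sharing the most canonical breakpoints (ties by smaller dissimilarity,
then id), reporting the link p-value, the inherited-breakpoint fraction,
and support at p ≤ 0.01.

# CNA landscape statistics

* **Event classification**: against reference state 2 (diploid) or 4
  (polyploid); below-reference runs are deletions; above-reference runs
  are gains unless state ≥ 2× reference *and* span ≤ 10 bins
  (amplification; the focality rule is a package decision — the field has
  no single printed definition).
* **Recurrent cores**: greedy Jaccard-sum extraction — a candidate (event)
  interval scores the sum over cells of its best same-class Jaccard
  overlap; the top interval is peeled out of the remaining events and the
  search repeats.  Significance permutes event positions uniformly within
  chromosomes, preserving lengths and per-cell counts.  This is an
  approximation to classical recurrence scoring; the greedy top core is
  verified against exhaustive search in the test suite.
* **Frequency tracks**: per-sample segment values centred to mean 1;
  gained at ≥ 1.1, deleted at ≤ 0.9, boundaries inclusive.
* **Homogeneity**: per-bin frequency of the modal integer state
  (single-cell mode); cf/purity per segment clipped at 1.25 (bulk mode,
  raw values kept in a diagnostic column), with gain and deletion
  distributions compared by a two-sample Kolmogorov–Smirnov test.  Note
  the per-bin score is non-monotone in alteration frequency — a rare
  subclonal gain leaves the *unaltered* modal state nearly fixed — so
  class comparisons should be made over recurrent (core) intervals, as the
  test suite does.
* **Group comparisons**: Welch t and Mann–Whitney U via the standard
  library routines (exact for small tie-free samples).

# Problem sizes and determinism

The test suite exercises the generator end-to-end at 400–1,000 bins for
unit checks and at the full 5,000-bin mouse geometry for the recovery and
phase-signature experiments (30–200 cells, one CPU, minutes per
experiment); these sizes were chosen so the whole suite reproduces the
pipeline's behaviour at the reference bin resolution while staying
desk-scale.  Every stochastic step takes an explicit seed; the pipeline
derives per-stage and per-cell streams from one root seed.

# Known limitations

* **Detection floor**: at per-bin CV ≈ 0.3, single-copy arcs below ~8 bins
  (diploid scale) or ~40–60 bins (tetraploid scale) sit at or below the
  CBS permutation test's power at `alpha = 0.01`, and ±1-bin localisation
  of a one-copy diploid step carries an irreducible ~10% error rate from
  boundary noise alone.  Consequently the breakpoint-recovery rate under
  the default noise hovers near, and can fall short of, 90% within ±1 bin.
* **2n/4n quantal ambiguity**: a doubled genome is identified only through
  odd-state (or otherwise scale-breaking) segments; doubled lineages with
  little detected post-doubling rearrangement can still be reported at the
  halved scale.  This is a property of sparse-coverage quantal fitting in
  general — experimental designs resolve it by DNA-content gating.
* **Clone sensitivity**: with clone signatures of only ~8 breakpoints and
  a strongly clonal background, whole-clade nodes can score FDR just above
  `t = 0.01` under the interchange null, fragmenting clones into accepted
  sub-nodes and singletons.  Signatures of ≥10 disjoint breakpoints
  separate cleanly.  The FDR threshold is deliberately left at the strict
  conventional value rather than relaxed.
* Equal-length bins ignore mappability variation; all downstream
  mathematics is bin-indexed, so replacing the scaffold with
  mappability-scaled bins is a drop-in change.
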