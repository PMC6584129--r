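---
title: "Binding-site composition and silencing analysis: methods"
author: "silencescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site composition and silencing analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silencescan)
```

# The problem

Bacterial nucleoid-associated proteins (NAPs) of the H-NS/Lsr2 family act as
xenogeneic silencers: they bind AT-rich DNA — which in a high-GC host marks
horizontally acquired or otherwise "foreign" sequence — and repress its
transcription. In *Streptomyces*, whose linear, ~72% GC chromosomes carry
dozens of specialized metabolic gene clusters (BGCs), this silencing is a
major reason many clusters are cryptic in the laboratory. A study of such a
silencer produces a characteristic set of desk computations, which this
package implements as reusable, tested functions:

1. Is bound DNA compositionally distinct from the genome baseline
   (AT-rich windows and cores, GC fraction)?
2. Which genes and clusters does each binding site plausibly regulate
   (upstream/overlap association)?
3. Are differentially expressed (DE) genes over-represented in clusters
   (binomial enrichment)?
4. Does raising the GC of a bound site - with or without destroying its
   AT-rich core - abolish the composition signal (variant design)?
5. Which volatile compounds shift between wild type and mutant
   (rank tests with FDR control)?

# Composition scanning

Two composition features define "AT-rich" here:

* an **AT-rich segment**: a window of `window_len = 20` nt containing at
  least `window_min_at = 11` A/T symbols. Eleven is the strict majority of
  twenty, i.e. the ">50% A/T" reading of the threshold; both parameters are
  exposed in `scan_config()` should a different convention be needed.
* an **AT-rich core**: any `core_len = 6` consecutive nucleotides of which
  at least `core_min_at = 5` are A/T.

`count_at_windows()` and `count_at_cores()` report two counts. The
*overlapping* count is the number of window start positions that qualify —
a smooth measure of AT density. The *disjoint* count is the size of a
maximum set of pairwise non-overlapping qualifying windows, the natural
reading of "number of non-overlapping stretches". It is computed by
earliest-end greedy selection, which is provably optimal for interval
scheduling; with equal-length windows, earliest end coincides with earliest
start. Tests confirm equality with an exhaustive include/exclude search on
short sequences.

`N` symbols count as neither A/T nor G/C. A window containing `N` can still
qualify if its A/T count alone meets the threshold; this is conservative in
the direction of the AT criterion. `gc_content()` likewise excludes `N`
from numerator and denominator, and is undefined (an error) for empty or
all-`N` input.

`sample_baseline_segments()` draws segments uniformly from the chromosome
under a seed, without regard to annotation — the baseline design is 15
segments of 500 bp and 15 of 1000 bp, but both the counts and the lengths
are parameters. Because the sampled coordinates are recorded, baseline
profiles are fully reproducible.

# Coordinates, clusters and regions

All internal coordinates are 1-based inclusive (the GFF convention); BED
input is converted at the boundary. Cluster definitions follow the
first-gene/last-gene convention of published cluster tables: membership is
a locus-*index* range (e.g. a cluster from locus 223 to locus 234 has 12
members), not a genomic interval. This matters because published
denominators are span counts; where a table's printed percentage implies a
different denominator than the inclusive span, `cluster_de_summary()` also
offers `member_mode = "explicit"`, which counts only loci present in a
supplied gene table. The bundled cluster table transcribes its source
verbatim, including internally inconsistent rows; the package recomputes
nothing in that file.

The left-arm/core/right-arm partition of the linear chromosome is
user-supplied configuration (`partition_regions()`), since arm boundaries
are genome-specific annotations rather than derivable quantities. The
partition must tile `[1, L]` exactly. Sites are classified by their midpoint
`floor((start + end) / 2)`; sites are small relative to regions, so
midpoint assignment and any-overlap assignment almost always agree, and the
midpoint rule gives every site exactly one region. A site whose midpoint
computation lands on a boundary resolves leftward (the floor).

# Site-to-gene association

A binding site is associated with a gene when it intersects the gene body,
or intersects the strand-aware upstream interval of `upstream_window`
nucleotides ending at the gene's 5' end. "Immediately upstream" is not a
quantified notion; the default of 300 nt is a typical bacterial
promoter-region scale and is configurable. Both relations are reported when
both hold, and a site between divergently transcribed genes associates with
both — the situation of a silencer sitting in a divergent intergenic region
and repressing both flanks. A site's `transcription_change` flag is true
iff any associated gene passes the DE filter; per-region summaries report
the fraction of sites with a change and mean site widths split by change
status (empty groups are `NA`, never silently zero).

# Differential expression and enrichment

The DE filter is deliberately strict and symmetric: a gene is significant
when `max(fc, 1/fc)` strictly exceeds 4 *and* `q` is strictly below 0.01,
with fold change oriented mutant/wild-type. Boundary values (fold change
exactly 4, q exactly 0.01) are excluded, matching the "greater than
four"/"less than 0.01" phrasing of the reference thresholds. When fold
change must be computed from expression means, a pseudocount (default 1
RPKM) guards against division by zero: silenced clusters genuinely have
wild-type RPKM near zero. q-values are consumed as given, never recomputed —
the upstream DE caller's multiple-testing model is out of scope.

Cluster enrichment is a one-sided binomial tail: with `n` DE genes of which
`k` fall in cluster spans, and a null proportion `p0` equal to the fraction
of loci inside the union of cluster spans (overlapping clusters merged, so
shared loci count once), `enrichment_binomial()` returns
`P(X >= k), X ~ Bin(n, p0)` via `pbinom(k - 1, n, p0, lower.tail = FALSE)`,
i.e. the regularized incomplete beta function, which is stable in extreme
tails; tests verify agreement with direct density summation to 1e-10
relative error up to `n = 1000`. The null proportion must usually be
*reconstructed*: with the bundled 30-cluster table, the merged spans cover
1021 loci of a 7455-locus chromosome, giving `p0 = 0.137`.

# Volatile metabolome pipeline

The display transform is per compound: log10, mean-center, unit-scale.
Unit scaling divides by the **population** (1/n) standard deviation of the
log values — so log10 values `{1, 2, 3}` become `{-1.2247, 0, 1.2247}` —
rather than the sample (n-1) standard deviation. Zero intensities are
replaced by half the compound's smallest positive value before the log
(missing-value imputation conventions vary across metabolomics software;
half-minimum is a common, conservative choice). Constant compounds cannot
be scaled and are excluded with a warning.

Testing uses the Mann-Whitney U test on the *raw* intensities. Because the
test is rank-based and the transform is strictly monotone per compound,
testing raw or transformed values gives identical p-values; the transform
exists for visualization. The exact null distribution is used when the
combined sample size is at most 12 and there are no ties; otherwise the
normal approximation with continuity and tie correction. Benjamini-Hochberg
correction is applied across compounds and selection is strict
(`adjusted p < alpha`, default 0.05); sterile-medium samples are excluded
from testing but kept for display.

A power caveat worth knowing: with 6 samples per group the smallest exact
two-sided p-value is `2 / choose(12, 6) = 0.00216`. After BH correction
over a few hundred compounds this sits very close to the selection
threshold, so recovery of a small planted-shift set is nearly
all-or-nothing — either most shifted compounds achieve complete group
separation and the whole block survives correction, or none does. At 6 vs 6
samples and a 3-standard-deviation shift the per-compound probability of
complete separation is about 0.7, so a 10-compound planted set clears BH in
roughly a quarter of random realizations. Larger designs (more replicates,
or a larger shifted fraction) escape this discreteness.

# Variant design

`raise_gc()` engineers the GC-raised probe variants used to test whether
binding tracks overall AT content or the AT-rich core specifically. Only
A/T→G/C substitutions are made; the substitution count is the nearest
integer to `target_gc * length`, so the achieved GC is always within ±0.5
percentage points of target for sequences of at least 100 nt (shorter
sequences where the rounding error exceeds the tolerance raise an error
instead). In `disrupt_cores` mode, positions are chosen greedily by the
number of qualifying core windows they sit in (ties leftmost), recomputed
after each substitution, until no core remains; any remaining budget is
spent on seeded-random A/T positions. In `spare_cores` mode only A/T
positions outside every qualifying core window are eligible, so all cores
survive; the mode errors if the eligible pool is smaller than the budget.
The replacement letter is G or C by a seeded coin flip (no strand or
stacking preference is assumed), and the full procedure is deterministic
under its seed. Protected intervals are never mutated. Lowering GC is out
of scope.

# Synthetic data: what it does and does not emulate

All generators are seeded and bit-reproducible, and each returns the truth
it planted.

* `simulate_chromosome()` draws i.i.d. letters at 72.4% GC with island
  positions redrawn at the requested AT fraction (default islands in the
  full scene: 300 nt at 60% AT, i.e. 40% GC — matching the observed ~35-40
  point GC deficit of bound sites relative to the chromosome). Each island
  is stamped with one guaranteed A/T 6-mer so that core detection on
  island-derived sites is testable as a near-certain event.
* `simulate_annotation()` packs non-overlapping genes left to right
  (log-normal length jitter around 900 nt with ~100 nt gaps, typical
  bacterial gene density) with locus numbering increasing along the
  chromosome, and places clusters as consecutive 40-gene locus blocks; the
  default scene has 8000 loci with 25 clusters (1000 cluster loci),
  mirroring the magnitudes of the reference chromosome.
* `simulate_de()` plants per-gene significance with probability 0.15 inside
  clusters and 0.04 outside. Planted genes get fold changes log-uniform in
  [4.5, 900] (a ~10% minority repressed) and q-values below 0.01; all other
  genes are sub-threshold on both criteria, so the planted set equals the
  `filter_de()` output *exactly* — recovery tests need no tolerance.
* `simulate_sites()` emits one site per island with jittered bounds and
  sub-0.01 q-values, plus uniform noise sites with q-values spread to 0.05
  so that site filtering has something to remove.
* `simulate_volatiles()` draws log-normal intensities (per-compound
  baselines log10-uniform in [4, 7], within-group sd 0.25 log10 units ~ a
  typical ~60% CV for GC-MS relative abundances) and displaces the shifted
  compounds' mutant mean by `shift_sd` within-group standard deviations,
  alternating direction; a medium group at 10-fold lower abundance is
  included for display only.

The i.i.d. background is a deliberate simplification. Real high-GC genomes
are compositionally heterogeneous — codon structure, strand skews, and
genuine AT-rich islands — so baseline counts measured on the synthetic
chromosome are *not* comparable to baseline counts on a real genome: an
i.i.d. 72.4% GC background yields an AT-rich core every few hundred bp,
whereas large stretches of a real *Streptomyces* chromosome contain none.
Passing recovery tests on synthetic scenes therefore demonstrates that the
algorithms measure what they claim (planted signal in, planted signal out),
not that real-genome baseline statistics are reproduced. That is also why
the study-scale checks in the test suite are property-level (enrichment
p-values, core recall) rather than value-level reproductions of printed
baseline counts.

Test problem sizes are chosen to keep the suite fast while staying at the
study's magnitudes where it matters: the enrichment-recovery check runs the
full 8000-locus annotation across 20 DE seeds, and the island-core check
uses 100 islands on a 400-kb chromosome.

# Numerical and degenerate-input conventions

* Strictness: every published threshold is applied strictly (`<`/`>`), so
  boundary values are excluded everywhere (site q = 0.01, fold change = 4,
  adjusted p = alpha).
* Sequences shorter than a window scan to zero counts, not an error; empty
  or all-N sequences make `gc_content()` error.
* Means over empty groups are reported as `NA`, never 0.
* `pct_up` is rounded to two decimals, matching the convention of printed
  cluster tables; nothing downstream consumes the rounded value.
* All seeded generators restore the caller's RNG state, so package calls do
  not perturb a user's random stream.

# Known limitations

* Peak calling, read alignment, and the DE caller's statistics are out of
  scope; the package consumes their tabular outputs.
* Cluster membership by locus-index span cannot represent interleaved or
  non-contiguous clusters; explicit membership lists cover those cases only
  insofar as a gene table is supplied.
* The region partition is configuration, not inference; no attempt is made
  to derive arm/core boundaries from composition.
* The volatile pipeline's sensitivity at very small group sizes is bounded
  by rank-test discreteness, as described above.
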