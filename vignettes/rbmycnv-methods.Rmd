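---
title: "Methods: copy-number estimation, event counting and selection tests for a multi-copy Y gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number estimation, event counting and selection tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmycnv)
```

# Scope

`rbmycnv` re-implements, as a tested pipeline, a published analysis strategy
for copy-number variation of the *RBMY1* gene family on the human Y
chromosome: depth-ratio copy-number estimation calibrated against fibre-FISH,
parsimony counting of copy-number change events on the Y-SNV phylogeny with
conversion to a per-transmission mutation rate, neutral-simulation and
direction-bias selection tests, and droplet-digital-PCR quantification. The
raw cohort data (1000 Genomes Y alignments and the curated phylogeny) are not
redistributable, so the package pairs every consumer with a synthetic
generator that produces inputs with the same statistical structure and full
ground truth.

# The read-pooling depth model

The six active *RBMY1* copies sit in four clusters ("regions 1–4", GRCh37
coordinates are the package defaults in `region_set()`). Copies are >98%
identical, so a read from *any* copy aligns essentially at random among the
reference copies: the summed depth over the reference footprint is
proportional to the *total* copy number carried by the sample, regardless of
which cluster expanded. The footprint also contains five pseudogenes short
enough to absorb roughly one gene-copy's worth of reads. Writing $f$ for the
ratio of mean depth over the four regions to the mean depth of a nearby
single-copy interval,

$$ f = \frac{\mathrm{CN} + p}{c}, \qquad c = 7,\; p = 1, $$

so $\mathrm{CN} = f c - p$, rounded to the nearest integer. One copy changes
the ratio by $1/7 \approx 0.14$. `rough_copy_number()` applies this map;
ratios 0.62 and 1.89 give 3 and 12 copies.

Depth is computed as the arithmetic mean of per-base depth in 5 kb
non-overlapping windows across Y:22–29 Mb (`load_depth_windows()`; absent
bases count as zero). Windows straddling a region boundary contribute to the
region mean with overlap-length weights — the coordinates are not aligned to
the window grid, and ignoring partial overlap would introduce window-phase
artifacts. The combined ratio is the pooled (length-weighted) mean over all
four regions divided by the reference mean, which makes it invariant to
uniform depth rescaling.

Samples whose reference depth is zero are reported as uninformative and
skipped, mirroring the exclusion of failed samples in the original workflow.
The manual "flanking depth constant" curation is operationalized by
`flag_curated()`: every window overlapping 100 kb on either side of the
region block (excluding the gene regions themselves) must lie within 25%
of the median flank depth. Both defaults are exposed; the original criterion
was a visual judgment, so we do not claim to reproduce its sample counts.

# Calibration against fibre-FISH

`fit_ols()` is plain ordinary least squares with intercept — no weighting, no
errors-in-variables — because that is the stated method of the analysis being
reproduced. The 14 fibre-FISH-validated samples ship as
`gold_standard_table()`; regressing their ddPCR totals on the fibre-FISH
totals gives $y = 0.9582x + 0.1943$, $R^2 = 0.98$ (the regression direction
with ddPCR as response is the one that reproduces those published
coefficients; the alternative direction does not). `split_validation()`
reproduces the 8-train / 6-test design: fit on eight samples, predict integer
copy numbers for the held-out six, tabulate exact / off-by-one / worse.

The published *ratio* calibration ($y = 0.4945x + 1.1504$) implies predictor
values near 8–24, which cannot be reconciled with combined ratios of
0.62–1.89 from the printed per-sample data; the exact definition of that
predictor is not recoverable. The package therefore fits its own coefficients
for whichever predictor convention the user configures, and those two printed
numbers are not used as a correctness reference.

# Counting copy-number change events on the phylogeny

Branch lengths of the input tree are SNV counts; tips carry integer copy
numbers. `min_event_labeling()` computes **unit-cost parsimony**: the minimum
number of edges on which the state changes, where a change of any magnitude
costs one event (a single mutational step can add or remove several tandem
copies, so magnitude-weighted costs would be wrong). The dynamic programme
runs over the alphabet of all integers between the smallest and largest
observed state (pass-through states allowed) and handles multifurcations
natively — real Y phylogenies contain large polytomies.

Besides one optimal labeling, the DP yields, per node, the full set of states
attainable in at least one globally optimal labeling. A node is *ambiguous*
when that set has more than one element. An event (edge with differing
endpoint states) is **confident** when both endpoints are unambiguous; only
confident events get a direction (sign of child − parent) and a magnitude
used in histograms. This is our operationalization of "events whose ancestral
state is clear" — the original rule is unstated, so confident-event counts
are a declared proxy, not a reproduction. Tie-breaks in the single reported
labeling prefer the parent's state (no spurious events), then the smaller
state.

`clade_mode_labeling()` implements the stated heuristic of assigning each
internal node the modal copy number of its subtree tips (ties resolve toward
the parent, root ties toward the global mode then the smaller state). Its
implied event count is never below the parsimony minimum (tested); both are
reported side by side rather than reconciled.

`filter_events()` applies the conservative filter (magnitude ≥ 2, both
endpoint states within [5, 12]). `scale_confident_histogram()` scales a
confident-event magnitude histogram up to the total event count with
largest-remainder rounding, so the scaled classes are integers summing
exactly to the total.

# From SNV branch lengths to a mutation rate

With SNV rate $\mu = 0.76\times10^{-9}$ /bp/yr (95% CI 0.67–0.86), callable
length $L = 10.3$ Mb and generation time $g = 30$ yr, one SNV corresponds to
$1/(\mu L) = 127.7$ years, i.e. $4.26$ generations. A tree with $S$ SNVs has
total branch length $G = 4.26\,S$ generations, and $K$ events give a rate

$$ r = K / G = K \mu L g / S $$

per father-to-son transmission (`cn_mutation_rate()`). The CI substitutes the
SNV-rate CI bounds — the rate is linear in $\mu$ — and deliberately does not
fold in Poisson uncertainty in $K$, matching how the published CIs were
constructed. For the genome-wide counts (562 events, 60 084 SNVs) this yields
$2.20\times10^{-3}$ (1.94–2.48 × 10⁻³); for the curated set (371 events,
48 900 SNVs), $1.78\times10^{-3}$.

`transmission_rate_ci()` gives the direct father–son estimate with an exact
Clopper–Pearson interval from Beta quantiles. For 1 mutation in 77
transmissions: point $1.3\times10^{-2}$, lower bound $3.3\times10^{-4}$.
The exact upper bound is $7.0\times10^{-2}$; the published value
($6.8\times10^{-2}$) is not reproducible by any standard exact interval that
also yields the published lower bound, and we keep the method faithful rather
than the digit.

# Selection tests

`direction_bias_test()` is the standard two-sided exact binomial test of the
decrease count against $p = 0.5$. Note that for the published direction
counts (99 decreases vs 77 increases) the exact two-sided p-value is 0.113,
not the published 0.015; none of the standard test variants we tried
reproduces the published p-values from the published counts, so p-values are
reported but not treated as a correctness reference.

`simulate_neutral()` implements the neutral null: the fixed inferred event
set (default: decreases of 1–5 copies with counts 227/54/16/13/3, increases
of 1–4 with 185/42/19/4) is scattered over the edges of the same tree with
probability proportional to branch length, independently per replicate; tip
copy number is the ancestral state (8) plus the signed path sum, negatives
floored to zero. This follows the original design of re-placing a *fixed*
event set rather than drawing a Poisson process. The across-tip variance per
replicate forms the null distribution; `variance_percentile_test()` ranks the
empirical variance in it (midranks for ties, linear-interpolation
percentiles) and calls `below_null` under the 0.5th percentile. The default
variance is the population (denominator $n$) variance; the original choice is
unstated, and a flag switches to the sample variance.

# ddPCR quantification

Template partitioning into ~20 000 droplets is Poisson, so channel occupancy
is $\lambda = -\ln(1 - \text{positives}/\text{total})$ and concentration is
$\lambda$ / droplet volume (0.85 nL by instrument convention; it cancels in
every copy-number ratio). Copy number is target concentration over the
concentration of a single-copy reference gene. Two allele-specific assays
split the family: the T-assay covers the four proximal copies, the C-assay
the two distal copies; the total is their sum. Replicates differing by ≥ 0.8
copies trigger a third replicate before a consensus (arithmetic mean of
concordant replicates — the original software merges wells instead, a
documented difference) is formed.

# The synthetic generator: what it emulates, and what it does not

* `simulate_tree()` draws a Yule or Kingman topology, rescales branch
  lengths so the total is a target number of generations, and draws SNV
  counts per branch as Poisson(generations / 4.26), so rate recovery
  exercises the full SNV-to-generation conversion.
* `evolve_cn()` places Poisson(rate × edge generations) events per edge with
  signed sizes from the inferred histogram, records every placement, and
  computes tip states with the zero floor (or reflecting bounds, used to
  emulate stabilizing selection).
* `emulate_depth()` realizes the pooling model at *window* resolution: every
  window overlapping a gene region carries base_depth × (CN + 1)/7, with
  optional Poisson resampling of each window's read mass. Because elevation
  is whole-window, the noise-free round trip through
  `region_depth_ratio()`/`rough_copy_number()` is exactly the identity for
  CN 0–20. Real data differ at boundary windows (partial elevation) and in
  GC/mappability structure, which the generator does not model; a green
  round-trip test establishes the estimator's algebra, not robustness to
  alignment artifacts.
* `emulate_droplets()` draws binomial positives at occupancies
  $\lambda_\text{ref}$ and $\lambda_\text{ref}\times$CN; it does not model
  rain, threshold mis-calling or volume variation.
* `make_father_son()` mutates each son with the per-transmission
  probability; fathers all start at the modal state 8 (no father CN
  distribution is published, and only mutation counts are scored).

Default scales (500-tip trees, ~250 000 total generations, ~550 events)
mirror the density of the real data (1218 samples, 255 850 generations,
562 events) while keeping every test fast on one CPU.

# Numerical conventions

* Rounding of copy numbers: nearest integer, ties away from zero, floored at
  0 — shared by the depth, calibration and ddPCR paths (base R's banker's
  rounding would map 6.5 and 7.5 both oddly).
* External BED is 0-based half-open; internal coordinates are 1-based
  inclusive to match published region coordinates; conversion is bit-exact.
* Largest-remainder rounding for histogram scaling (scaled classes sum
  exactly to the target; remainder ties resolve to the earlier class).
* Percentiles use R's default linear interpolation (type 7); empirical ranks
  use midranks for ties.
* All generators are seed-deterministic; the pipeline derives per-stage
  substreams from one global seed, kept below 2³¹.

# Known limitations

* Unit-cost parsimony is a *minimum*: multiple events on one edge, equal
  events on sibling edges, and back-mutations are invisible. On synthetic
  500-tip trees at the real event density the parsimony count recovers only
  ~0.4× of the true simulated event count (~0.8× at a quarter of that
  density) — the acceptance script measures this (`rate_recovery_ratio_*`).
  Tree-based rate estimates inherit this downward bias, which is why the
  original analysis itself calls its rate a minimum estimate.
* The published event counts (562/371, 99/77) and the real-tree null
  variance interval depend on the unreleased curated phylogeny and manual
  curation, and are consumed as inputs, not reproduced.
* Depth-based copy numbers assume free mis-mapping among copies and a clean
  single-copy normalizer; structural variants in the flanks violate this,
  which is what the curation flag screens for.
* The confident-event rule and the clade-mode tie-breaks are declared
  conventions for under-specified steps; results that depend on them are
  labelled as such.
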