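---
title: "Nanocluster topography analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanocluster topography analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotopo)
```

`nanotopo` quantifies the nanoscale and mesoscale organization of membrane
receptors from localization-microscopy data. This vignette explains the
statistical models behind each stage, the tunable parameters and their
defaults, the design decisions taken where several reasonable constructions
exist, and what the synthetic benchmarks do and do not demonstrate about
real data.

## The data and its pathologies

A STORM acquisition yields a **localization table**: one row per fitted
fluorophore appearance, with frame number, position (nm), photon count and
fit width. Two properties make naive cluster analysis unreliable:

1. **Overcounting.** A single molecule blinks several times, producing
   multiple localizations scattered by the localization precision
   (~10–20 nm). Temporal grouping and photon-weighted merging
   (`group_time_contiguous()`, `merge_weighted()`) collapse appearances in
   time-contiguous frames within one pixel into a single record whose
   position is the photon-weighted mean — brighter appearances are localized
   better, so they earn more weight — and whose photons are the sum (exact
   conservation is asserted in the tests).
2. **Heterogeneous density.** Receptor density varies strongly across a ROI,
   so any fixed distance-and-count threshold (the DBSCAN recipe) is biased.
   The clustering below instead calibrates itself per ROI.

## Graph-based nanocluster detection

Localizations become nodes of an undirected graph with an edge wherever
either point is among the other's `K` nearest neighbours (`K = 10` by
default), weighted by a Gaussian kernel:

$$ w_{ij} = \exp\!\left(-\,d_{ij}^2 / r_o^2\right), $$

where the ROI-specific length scale $r_o$ is the **median K-th-nearest-
neighbour distance** over all localizations. Both choices deserve comment,
because published descriptions of kNN-graph clustering leave the exact
kernel and heuristic open: the Gaussian kernel is the standard similarity
on kNN graphs, maps coincident points to weight 1 and decays smoothly on the
scale the data itself sets; the median (rather than mean) K-th-NN distance
is robust against the short-distance tail that the clusters themselves
create. Both are contracts of this package, fixed by tests (two points at
distance $r_o$ with `K = 1` carry weight $e^{-1}$), not claims about any
external implementation.

**Noise removal.** Each node is scored by its summed incident edge weights.
The decision threshold is the $(1-\alpha)$ quantile of node scores pooled
over 20 CSR reference fields simulated with the *same* n, region, K and —
deliberately — the same $r_o$ as the data graph: holding $r_o$ fixed makes
the reference scores exchangeable with the data scores under the CSR null,
so a completely randomly placed localization is classified as clustered
with probability at most α (default 0.05). This is an explicit Monte-Carlo
calibration rather than an analytic null so that it remains valid for any
region shape. Survivors are re-graphed with a freshly estimated $r_o$.

**Communities and robust merging.** Clusters are communities of the
survivor graph found by weighted multi-level modularity optimization
(igraph's Louvain implementation; the literature uses Infomap- and
Louvain-family methods interchangeably here, and modularity multi-level is
the deterministic, widely available choice). Modularity methods over-split
dense blobs, so a dedicated merge step follows: two communities are merged
only if the subgraph induced by their union stays connected across the two
groups after deletion of *any single node* — equivalently, at least two
node-disjoint paths join them. This deterministic worst-case reading
implies robustness under any random single-node removal, which is the
behaviour the merge is meant to guarantee; a single shared "bridge"
localization is never allowed to fuse two clusters. Finally, clusters with
fewer than `min_cluster_size` members (default 15) are relabelled noise.

Determinism: the pipeline orders nodes canonically by coordinates before
building the graph, so the labelling is invariant to input row order, exact
under a fixed seed, and equivariant under uniform coordinate scaling (all
asserted in the tests).

## Alpha-shape similarity merging

The combined route applies an inter-cluster similarity based on
computational geometry to the **second level (counted from the coarsest)**
of the community hierarchy. Counting from the coarsest is itself a decision
— hierarchy orientation is a perennial ambiguity — and the second level is
the first one that meaningfully over-splits, which is what the merge needs
as input.

For a cluster pair $(A, B)$ the package triangulates $A \cup B$ and takes
the **alpha-complex at the smallest alpha on the Delaunay critical-value
ladder that encloses every point of the smaller cluster** (smaller target =
tightest shape = most conservative merging). The similarity is the number
of complex edges joining a point of $A$ to a point of $B$, divided by
$\min(|A|, |B|)$. This statistic is symmetric, scale-free, and exactly zero
whenever the minimal enclosing shape leaves a gap between the clusters —
well-separated clusters therefore never merge. The exact normalization is a
design decision of this package: any statistic with those three properties
would serve, and the tests pin this one down.

Merging then iterates: compute all pairwise similarities, merge the single
globally-maximal nonzero pair, recompute only the similarities involving
the merged cluster (lazy invalidation preserves the global-maximum rule),
and stop when all similarities are zero. Each iteration reduces the cluster
count by one, so termination is structural. The size filter runs last.

On fields with elongated or adjacent planted clusters this combined route
produces smaller median cluster areas, higher intra-cluster densities and
no larger eccentricities than graph clustering alone — asserted as a
direction, not a factor, because the magnitude depends on the geometry of
the input.

## Cluster metrics

- **Area** uses a concave boundary polygon built from the alpha-complex,
  with a shrink factor interpolating along the critical-alpha ladder:
  0 = convex hull, 1 = the tightest single boundary still enclosing every
  point. The default 0.5 mirrors the convention of MATLAB-style `boundary`
  areas; it is configurable and logged because no universal value exists.
  Density is defined as `n / area`, exactly.
- **Shape** comes from a farthest-pair ellipse fit: the farthest point pair
  fixes the major axis $2a$; after rotating the pair horizontal, the
  vertical span fixes $2b$; $e = \sqrt{1-(b/a)^2}$. Unlike a direct
  least-squares conic fit — which is retained as `ellipse_fit_lsq()` for
  cross-checks but is unstable on small clusters, returning axes that can
  exceed the cluster dimensions — the farthest-pair axes are bounded by the
  data by construction. The fit is rigid-motion invariant and
  scale-equivariant.
- **Inter-centroid distances** are restricted to Delaunay-adjacent centroid
  pairs, discarding biologically irrelevant long-range pairings; with two
  clusters the single distance is used. Whether published tables use
  all-pairs or triangulation-restricted distances is ambiguous; the
  Delaunay convention is this package's decision, consistent with the
  inter-particle statistic.
- **Region tagging** normalizes each localization's distance to the cell
  outline by the maximum such depth; depth ≤ 0.3 is peripheral, ≥ 0.5
  central, the band between stays untagged so the two ROI classes are
  disjoint by construction.
- All per-cluster summaries report the **median with a distribution-free
  95% CI** from binomial order statistics (lower rank
  `qbinom(0.025, n, 1/2)`, upper its mirror) — no normality assumption, and
  the CI collapses correctly for constant data.

## Spatial statistics

The nearest-particle function is the empirical
$G(d) = n^{-1}\sum_i I(d_{\min}(p_i) < d)$ with **strict** inequality, kept
exactly as the defining formula (boundary ties are excluded). The grid is
256 evenly spaced distances from 0 to the 99th percentile of the
nearest-neighbour distances — the top percentile is omitted because a
single isolated point otherwise stretches the axis. Envelopes are the
pointwise 2.5%/97.5% quantiles of G over 99 CSR simulations matched in n
and region; pointwise (not simultaneous) bands are what the 95% CI wording
of this analysis tradition implies. No edge correction is applied, matching
the plain empirical G; this gives a small negative bias at large d for
small samples, noted as a known limitation. The **maximum distance of
considerable clustering** is the end of the contiguous exceedance run of G
above the upper envelope starting at the smallest exceeding distance, and
is absent when G never leaves the band — with pointwise bands a CSR pattern
can graze the envelope, so the statistic is read comparatively, not as a
significance test.

## Photon-threshold mesoscale filtering

Direct (STED-like) imaging detects whole aggregates; the hypothesis behind
the mesoscale filter is that these correspond to the *brightest* STORM
localizations. `threshold_scan()` filters the table at a ladder of photon
thresholds — by default 20 quantiles evenly spaced in probability from 0 to
the largest threshold that leaves at least 20 survivors (a floor chosen for
triangulation stability) — computes the median Delaunay inter-particle
distance of each survivor set, and picks the threshold whose median is
closest to the STED-derived target (ties go to the smaller threshold, i.e.
to keeping more data). The survivors are then re-clustered with reduced
parameters `k = 2` and minimum cluster size `m = 2`; published parameter
listings give `k` and `m` without defining `m`, and this package interprets
it as the minimum cluster size of the reduced run — the natural reading for
survivor sets of a few dozen points. A uniform thinning that keeps a
fraction *p* of a CSR field stretches the median spacing by $1/\sqrt p$,
which fixes the direction of the scan and is asserted in the tests.

## The synthetic generator: what it emulates, what it does not

The generator plants disc-uniform clusters (optional axis-ratio elongation)
whose exclusion zones — discs of twice the cluster radius — neither overlap
nor cross the region boundary, over a CSR background. Blinking is modelled
as `1 + Poisson(reappearance_rate − 1)` appearances per molecule: every
molecule is seen at least once, which keeps ground-truth recovery
well-posed while still producing overcounting. Photon counts are lognormal,
parameterized by mean and CV — strictly positive, heavy-tailed like
experimental photon distributions, and able to express the bimodal
dim/bright mixtures the mesoscale tests need. Frames render each appearance
as an integrated 2D Gaussian whose pixel sum equals the photon count (the
tests assert conservation to 0.5%), with optional per-pixel shot noise and
Poisson background.

Default scales follow the nanocluster regime these experiments report:
clusters of ~20–25 molecules with areas of order 10³ nm² (radius ~50 nm),
fields of 10 × 10 µm at tens of molecules per µm². No quantitative blinking
model is available from the source material, so the defaults are calibrated
to those scale ranges only, not to any dye's photophysics. The generator
deliberately omits dipole/defocused PSFs, sCMOS noise maps, stage drift and
3D — passing tests therefore demonstrate correctness of the *algorithms*
under a clean generative model, not robustness to every instrumental
artifact; drift-corrected input is assumed throughout.

The mesoscale fixture (`simulate_mesoscale_field()`) places dim
nanoclusters on a ~400 nm lattice and adds a few very bright localizations
at "core" clusters on a ~3.3 µm site grid, emulating brightness that is
correlated with coarse-scale structure; its matching synthetic STED
reference is one spot per site.

## Numerical choices and degenerate inputs

- Delaunay triangulation is an in-package Bowyer–Watson implementation
  (Rcpp) on coordinates rescaled to the unit box; it is validated against a
  brute-force empty-circumcircle oracle in the tests. Duplicate points and
  collinear inputs raise classed errors (`nt_degenerate`); the alpha-shape
  routines fall back to a segment-chain shape for collinear clusters, and
  collinear centroid sets fall back to consecutive gaps.
- kNN queries use a uniform-grid cell list with expanding ring search and an
  exact termination bound, falling back to the quadratic scan below 256
  points; results are exact, not approximate.
- Gaussian fits (elliptical, then rotationally symmetric integrated) use
  Nelder–Mead least squares with log-parameterized widths and amplitudes;
  weights are `1/max(counts, 1)` for the integrated fit. Non-convergent or
  out-of-window fits are dropped and counted, never silently kept.
- Multi-emitter rejection defaults to ellipticity ≤ 1.3 and fit width in
  [0.5, 2] × PSF σ. The filter is named, but not quantified, in the source
  methods; these cutoffs are this package's defaults and are configurable.
- STORM peak thresholds default to 1.0 × the standard deviation of the
  filtered image, reading the upstream tool's "std of the first wavelet
  level" semantics; the fit window is 7 px (the safer end of the 5–7 px
  range at simulated signal levels).
- Ties: threshold scan ties resolve to the smaller threshold; grouping ties
  join the nearer previous-frame particle; the merge loop takes the first
  maximal pair in index order.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make the
Monte-Carlo assertions sharp while keeping a full run in the minutes range
on one core: CSR calibration uses ten independent 10 × 10 µm fields at 50
molecules/µm² (~5,000 localizations each, 20 reference simulations per
field); recovery uses 20 planted clusters of 25 molecules; envelope checks
use 99 CSR simulations; the mesoscale fixture holds ~12,500 localizations.
These sizes are the package's validation conditions, not limits of the
implementation — the grid kNN and triangulation handle fields an order of
magnitude larger.

## Known limitations

- G(d) carries small-sample boundary bias (no edge correction, by design).
- The noise-removal calibration bounds the *expected* clustered fraction on
  CSR by α; individual fields fluctuate around it.
- Connected-component STED detection reports one particle for two spots
  fused into a single component — inherent to the method and documented in
  its tests.
- The alpha-shape similarity and the kNN kernel are contracts of this
  package (fixed by its tests), chosen to satisfy the qualitative
  properties the methods literature states, not reverse-engineered
  reproductions of any specific external implementation.
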