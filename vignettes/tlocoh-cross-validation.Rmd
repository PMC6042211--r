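---
title: "Cross-validated parameter selection for T-LoCoH home ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated parameter selection for T-LoCoH home ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locohcv)
```

## The model

T-LoCoH estimates an animal's utilization distribution from a time-ordered
sequence of projected GPS fixes. Around every fix (the *parent*) it builds
the convex hull of the parent's $k$ nearest neighbours under the linear
time-scaled distance

$$\mathrm{TSD}(a,b) = \sqrt{(x_a-x_b)^2 + (y_a-y_b)^2 +
  \big(s\, v_{max}\, (t_a-t_b)\big)^2},$$

where $v_{max}$ is the maximum observed speed over consecutive fixes and
$s \ge 0$ converts elapsed time into an equivalent displacement
($s\,v_{max}\,\Delta t$ is the maximal distance travelable in $\Delta t$,
shrunk by $s$). With $s=0$ the TSD is the Euclidean distance and the method
is purely spatial; with $s>0$, fixes from temporally distant revisits of
the same place are pushed apart, so hulls respect visit structure. In this
package $k$ counts the parent itself, which makes $k=n$ (every hull equal
to the global hull) exactly reachable and guarantees at least three
non-parent members at the grid floor $k=4$.

The hullset is turned into a probability density by normalization: a
location covered by $g$ of the hulls has density $g/A$, where
$A=\sum_h \mathrm{area}(h)$ is the **summed** hull area, overlaps counted
multiply. (Each hull contributes a uniform density $1/A$ on its interior;
stacking is what encodes intensity, which is why $A$ is a sum and not a
union.) This density integrates to exactly 1 over the plane.

## The cross-validation score

The trajectory is split $n$ times into training and testing fixes; for
each split $i$ the training hulls are built at the candidate $(k,s)$ and
each test point $j$ is scored by its log density,

$$P_{k,s} = \sum_{i=1}^{n}\sum_{j=1}^{m}
  \log\!\left(\frac{g_{i,j}}{A_i}\right),$$

with natural logarithms throughout (the score is only ever compared to
itself, but the base must be fixed). A test point covered by no hull would
give $-\infty$, so it is assigned probability $1/A_i^2$ instead: for
$A_i>1\,\mathrm{m}^2$ this is strictly below the density of any covered
point, so misses are penalized but finite. Both failure directions are
therefore punished without an explicit complexity term: too-small $k$ (or
too-large $s$) produces slivers that miss the test points and hit the
fallback; too-large $k$ inflates $A_i$ and deflates every $g/A_i$ — in the
limit $k=k_{max}$ all hulls coincide with the global hull and each test
point's density collapses to the inverse of the global hull area.

### Numerical and degenerate-input choices

* **Units.** All internal geometry is in m²; the fallback $1/A^2$ is not
  scale-invariant (below 1 m² it would out-rank $1/A$), so scoring a
  hullset with $A \le 1\,\mathrm{m}^2$ is a hard error rather than a
  silent misordering. Real home ranges are many orders of magnitude above
  this; hitting the guard almost always means unprojected coordinates.
* **Degenerate hulls** (collinear or coincident members) are kept with
  area 0; they add nothing to $A$ and cannot cover a test point. A
  hullset that is entirely degenerate is an error surfaced to the caller.
* **Containment is boundary-inclusive** (relative tolerance $10^{-9}$), so
  a parent lying on its own hull's boundary is always enclosed.
* **Ties.** Neighbour ties in TSD break to the smaller fix index; the best
  grid cell is the highest score, then the smaller $k$, then the smaller
  $s$ (parsimony: the finer model must strictly win). Both rules exist for
  bit-level determinism across runs and platforms.
* **$v_{max}$ is computed once on the full trajectory** and reused for
  every training subset, keeping the TSD geometry — and hence the meaning
  of $s$ — identical across splits. A config override exists for users who
  want to pin $v_{max}$ (e.g. to trim speed outliers; the package does no
  outlier filtering itself).

### Splits

How the original training/testing split was constructed is not restated in
the source commentary, so both implemented modes are this package's
choices, recorded in all outputs: `random` (default; per split, a seeded
random 25% of fixes is held out, 5 splits) and `temporal-blocks` (split
$i$ holds out the $i$-th of $n$ contiguous time blocks, which tile the
track — appropriate when temporal autocorrelation between train and test
is a concern). A warning is emitted when more than half of all test points
fall outside every hull, since the score is then fallback-dominated.

## The coarse-to-fine search

The default grid covers $s \in [0, 0.05]$ and $k \in [4, 800]$, searched
in three stages: (1) the full coarse grid, $k$ step 20 and $s$ step 0.01
(240 cells); (2) $k$ within $\pm 20$ of the peak at step 5, coarse $s$;
(3) $k$ within $\pm 5$ of the stage-2 peak at step 1, with $s$ refined at
step 0.001 within one coarse step of the stage-2 best (a finer $10^{-4}$
step is available via `search_config(s_step_fine = 1e-4)`). Windows are
clipped to the legal grid and to the training size; previously evaluated
cells are reused, which is exact because scoring is deterministic.

**Known limitation.** The staged search assumes the coarse surface points
toward the global optimum. On strongly multi-patch tracks the fine-scale
score is discontinuous in $k$ — a one-unit change can make hulls snap
across an inter-patch gap and shift the score by tens of log units — and
any coarse-to-fine scheme (including the published one this reproduces)
can then settle on a near-optimal but not globally optimal cell. The
acceptance test for search correctness therefore uses single-patch
fixtures, whose surfaces are effectively unimodal; on rugged surfaces the
staged result is best read as "a good cell near the peak", and an
exhaustive scan of a reduced grid is the fallback when exactness matters.

## Derived outputs

* **Isopleths.** Hulls are sorted by enclosed-fix count (descending; ties
  by smaller area, then smaller parent index — the usual point-density
  ordering) and accumulated until $\lceil \mathrm{level}\cdot n\rceil$
  distinct fixes are covered. The reported area is the exact dissolved
  union area (a vertical-slab sweep over the selected convex polygons;
  overlaps counted once), in km². Because no polygon-clipping library is
  part of this package's dependency footprint, the isopleth *geometry* is
  exported as the selected hulls themselves (a possibly-overlapping
  MultiPolygon) with the union area attached as a property. The default
  level is 0.95 and is always recorded in outputs; the source commentary
  does not state the level behind its published areas.
* **Visit metrics.** A hull's enclosed fixes are segmented into visits
  wherever the time gap exceeds the inter-visit gap `ivg`; NSV is the
  visit count and MNLV the enclosed count divided by NSV, so
  $\mathrm{NSV}\times\mathrm{MNLV}$ equals the enclosed count exactly.
  `ivg` defaults to 86 400 s (at most one visit per day) — no canonical
  value exists, and published tables used an unstated one, so reported
  metrics are only comparable at equal `ivg`. Doubling `ivg` can only
  merge visits, never split them.

## What the simulator does and does not emulate

`simulate_track()` generates the two features the score is sensitive to:
spatial clustering (isotropic Gaussian scatter, default sd 150 m, around
patch centres) and timed revisits (a dwell schedule over patches a few km
apart, connected by straight-line travel at `travel_speed`, default
1 m/s, discretized at the fix interval `dt`, default 3600 s). Defaults
give ~2900 fixes, matching the order of magnitude of typical collar
deployments. By construction $v_{max}$ of a simulated track approximates
`travel_speed`, which makes the $s$ grid interpretable on fixtures.

Not emulated: autocorrelated within-patch movement, tortuous travel,
irregular or missed fixes, location error, drifting patch use. A green
test on simulated data therefore establishes that the estimator and
search behave correctly on tracks with clean cluster/revisit structure —
not that any particular ecological conclusion transfers to field data.

## Reproducibility

Every stochastic component (simulator, random splits) takes an explicit
integer seed and restores the caller's RNG state. Identical inputs and
seeds give bit-identical score surfaces, simulated tracks and CLI JSON
outputs; each CLI run writes a RunRecord with the effective configuration,
seed, package version and an md5 digest of its input.
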