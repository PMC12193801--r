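---
title: "Quantifying sessile-cell morphodynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sessile-cell morphodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

## The problem

Resident tissue macrophages and similar sessile immune cells do not
migrate: they keep a stationary core anchored in the tissue and sample the
surrounding interstitial space with membrane protrusions that extend and
retract on a timescale of minutes. Their functional state is therefore
encoded less in where they go than in *how their shape changes*.
`morphodyn` turns 2D time-lapse movies of such cells (typically
probability maps from a pixel classifier, projected from intravital
two-photon stacks) into a vector of 31 interpretable morphodynamic
quantifiers per cell, and provides the population-level statistics needed
to compare experimental conditions in that 31-dimensional space.

The pipeline has four stages, each usable on its own:

1. **Segmentation and labeling** — probability movie to per-cell binary
   movies.
2. **Per-frame features** — size, shape and protrusion measurements for
   each cell and frame.
3. **Summaries** — each cell's time series collapsed into 31 quantifiers.
4. **Population statistics** — per-quantifier permutation Welch tests, an
   exact multivariate cross-match test, and a PCA morphospace.

A ground-truthed synthetic-movie generator (stage 0, in effect) makes all
of this testable without any microscopy data.

## Segmentation and labeling

The input is a movie of per-pixel foreground probabilities in [0, 1] (raw
intensities work too). Per frame:

* **Binarization** uses Li's iterative minimum-cross-entropy threshold:
  starting from the frame mean, the threshold `t` is replaced by
  `(mu_fg - mu_bg) / (log mu_fg - log mu_bg)` until convergence, where
  `mu_bg`, `mu_fg` are the means below/above `t`. Thresholding is
  per-frame by default; a global option pools all frames for movies with
  flickering exposure. Constant frames have no threshold and are returned
  empty with a warning.
* **Cleanup**: binary opening with a disk of radius 0.6 µm, then filling
  of holes smaller than 10 µm², then removal of objects smaller than
  10 µm². The hole filter runs before the object filter; since hole
  filling only adds foreground and the object filter only removes whole
  components, the two orders differ only for pathological masks, and this
  order is idempotent together with the opening.
* **Seeding**: the movie's temporal mean is thresholded at 0.97 — a pixel
  must be foreground in at least 97% of frames — and components smaller
  than 50 µm² are dropped. Sessile cells guarantee that each cell core
  survives this integration while debris and transient structures do not.
* **Two-pass watershed**: (i) seeded watershed of the cleaned foreground
  from the seed labels; (ii) the cleaned frame is dilated with a diamond
  of radius 2.2 µm and the watershed is repeated with the labels of (i)
  as seeds, which re-attaches protrusion fragments that binarization
  disconnected from their cell (anything within twice the dilation radius
  of its parent); (iii) the result is intersected with the cleaned frame.
  Foreground unreachable from any seed stays background rather than being
  force-assigned: an unattributable fragment should not silently inflate
  a cell. The elevation surface is the negated probability map when
  available, otherwise the negated distance-to-background transform; ties
  during flooding are broken first-in-first-out so results are
  deterministic.
* **Curation** replaces interactive proofreading with a file-driven spec
  (`{"merge": [[2, 3]], "exclude": [7]}`): merge groups unify to the
  smallest id, exclusions become background, labels are renumbered
  consecutively, and border-touching labels are reported in the log so
  the user can decide about cells cut off by the frame.

All physical parameters are given in µm/µm² and converted to pixels by
rounding radii to the nearest integer of at least one pixel; the pixel
size is instrument-specific and deliberately has **no default**.

## Per-frame features

For a binary mask with pixel area `A` (µm²) and estimated perimeter `P`
(µm):

| feature | definition | range |
|---|---|---|
| area | pixel count × pixel size² | > 0 |
| perimeter | sub-pixel iso-contour length (below) | > 0 |
| solidity | `A / A_hull` | [0, 1] |
| convexity | `P_hull / P` (same estimator on the rasterized hull) | [0, 1] |
| circularity | `4 pi A / P^2` | [0, 1] |
| aspect ratio | minor/major axis of the inertia-equivalent ellipse | [0, 1] |
| angularity | relative area lost by opening with a 1.0 µm disk | [0, 1] |

### The perimeter estimator

Perimeter estimation on rasters is the one place where naive methods fail
badly: counting pixel edges overestimates smooth outlines by up to a
factor 4/π (a digital disk has an "edge perimeter" of 8r, not 2πr), and
fixed-direction Crofton-type averages underestimate axis-aligned shapes
by several percent (a square of side s comes out near πs(1+√2)/2 ≈ 3.79s
with four directions). Neither keeps circularity and convexity in their
expected ranges for both squares and disks.

We therefore measure the length of the 0.5 iso-contour of the
Gaussian-smoothed mask, via marching squares with linear interpolation.
Smoothing cancels the rasterization staircase, while the 0.5 level keeps
straight edges at their true position. The smoothing scale
(`perimeter_sigma_px`, default 1.0 px) was calibrated once against
analytic shapes: a 100 px square measures 396.6 (true 400, −0.9%) and
digital disks of radius 20–50 px come out within +0.4% of 2πr, giving
circularity ≥ 0.99 for disks and π/4 ± 0.02 for squares. The cost of the
smoothing is that structures thinner than about 2 px fall below the 0.5
level and vanish from the contour; features should be computed at a
resolution where protrusions are at least 2 px wide. Convexity uses the
same estimator on the rasterized convex hull (hull of the pixel corners),
so estimator bias cancels in the ratio; for convex masks the hull equals
the mask and convexity is exactly 1.

### Fixed and mobile area

The *fixed area* is the set of pixels occupied in at least 97% of frames
(the same threshold as seeding — for a sessile cell this is its
stationary core); the *mobile area* per frame is the cell area outside
the fixed mask. The mobile/fixed ratio is the package's proxy for
sampling activity. The comparison `occupancy >= 0.97` is evaluated with a
1e-9 tolerance so that a pixel present in exactly 97 of 100 frames counts
as fixed.

### Protrusion features

* **Maximum protrusion length** is the directed Hausdorff distance from
  the cell boundary to the fixed-area outline (maximum over cell boundary
  pixels of the distance to the nearest fixed-outline pixel). It is
  unsigned: a cell shrunk inside its fixed area also scores a positive
  length.
* **Protrusiveness** is a Sholl-style count: concentric circles with
  radii 8, 16, 24, … µm are drawn around the centroid of the *fixed*
  mask (the stable reference point of a sessile cell, exposed as config),
  up to the cell's maximal radial extent; on each circle the number of
  connected arcs intersecting the filled cell body is counted, with
  angular wraparound, and the counts are summed. A filled disk of radius
  20 µm scores 2 (one arc on each of the 8 and 16 µm rings); a 4-armed
  cross with 20 µm arms scores 8.
* **Dynamic area change (DAC)** is the area of the symmetric difference
  between the cell masks at frames `t` and `t + lag`, with the lag equal
  to 14 s rounded to the nearest frame count (minimum 1 frame; the actual
  lag in seconds is recorded, since frame intervals differ between
  experiments).

Empty frames make a cell's features undefined; they are flagged, never
imputed, and a cell with any flagged frame is excluded from summaries.

## The 31 summary quantifiers

For each of the nine per-frame series (area, perimeter, solidity,
convexity, circularity, aspect ratio, angularity, max protrusion length,
protrusiveness):

* `mean_*` — arithmetic mean (average morphology),
* `var_*` — sample standard deviation divided by |mean| (dynamics,
  normalised to remove size dependence; a `raw_sd` switch disables the
  normalisation),
* `trend_*` — ordinary least-squares slope against time in seconds
  (active adaptation; computed on raw feature values, not normalised
  ones).

Plus four dynamic quantities: the fixed area, the mean mobile area, the
mobile/fixed ratio, and the OLS slope of the cumulative DAC sum (µm²/s).
That makes 9 × 3 + 4 = 31, in a fixed documented column order
(`summary_quantifier_names()`).

## Population statistics

**Permutation Welch test.** For each quantifier, Welch's unequal-variance
t statistic with a permutation null: group labels are randomly permuted
`n_permutations` times (default 10⁴) and the two-sided p-value is
`(1 + #{|t*| >= |t_obs|}) / (B + 1)`. The test is deterministic given a
seed. The 31 per-quantifier tests are *not* corrected for multiple
testing by default, mirroring per-panel reporting conventions;
Benjamini–Hochberg can be applied downstream.

**Cross-match test.** To ask whether two cell populations differ as
*distributions* in the 31-dimensional space, the pooled observations are
paired by an exact minimum-total-distance perfect matching under the
standardized Euclidean distance (each coordinate scaled by its pooled
SD; zero-variance coordinates are dropped with a warning). The statistic
`a1` counts pairs that join the two groups: separated distributions
produce few cross-matches. Under the null that group labels are
exchangeable, `a1` has the closed-form distribution
`P(A1 = a1) = 2^a1 (N/2)! / (C(N, m) a0! a1! a2!)` and the reported
p-value is the exact lower tail `P(A1 <= a1)`. An odd pooled size is
handled by adding a ghost point at distance zero from every real point
and discarding its pair, with the null computed on the reduced sizes.

The matching is solved exactly with an implementation of Edmonds'
weighted blossom algorithm (no greedy fallback); on all instances with
N ≤ 12 it reproduces the optimum found by exhaustive enumeration,
including tie-heavy integer weights.

One statistical subtlety is worth knowing: for even, equal group sizes
`a1` moves on a lattice of step 2, so the exact test's attainable sizes
are coarse — at m = n = 20 the lower-tail p jumps from 0.0075 directly
to 0.069, and "rejection at α = 0.05" occurs far less often than 5% under
the null. The result object therefore also carries `p_value_approx`, a
smooth normal approximation based on the closed-form null moments
`E[A1] = mn/(N-1)` and
`Var[A1] = 2m(m-1)n(n-1)/((N-3)(N-1)^2)`, whose rejection rate is close
to nominal. The exact p-value is the primary result.

**PCA morphospace.** Quantifiers are z-scored (they carry mixed units)
and decomposed by PCA; the sign of each component is fixed so its
largest-magnitude loading is positive, making scores invariant to row
order. Loadings, explained-variance ratios and per-cell scores are
exported in a flat CSV schema. Densities in the 2D score plane are
Gaussian product-kernel estimates on a shared grid with pooled
Silverman bandwidths, so conditions are directly comparable; each
condition's density integrates to 1 over the grid within 1%.

## The synthetic-data generator

A synthetic cell is a temporally fixed elliptical core (default semi-axes
8 × 6 µm) with K capsule-shaped protrusions (default 5, full width
2.5 µm) whose lengths follow `L_k(t) = L0 + A sin(2 pi t / T_p + phi_k)`
(defaults L0 = 8 µm, A = 4 µm, T_p = 120 s), rasterized at a configurable
pixel size (default 0.55 µm) and frame interval (default 14 s) for a
10-minute movie. These defaults are plausible desk-scale geometry for a
tissue macrophage, not measured values. The capsule axis starts half a
width *inside* the core boundary, so the rounded tip reaches exactly
`r0 + L` and the lobe vanishes completely as `L → 0`; the per-frame area
has a closed form (ellipse + bar + cap segments, neglecting the
O(w³/R) base-curvature overlap) that the rasterization tracks within 3%
at 0.3 µm/px. All randomness (protrusion angles and phases, map noise)
flows through one seeded generator per call, so movies are bit-identical
given a seed.

A *tissue* movie places several such cells on one canvas and converts
the union to a probability map: foreground 0.9, background 0.1, Gaussian
blur (σ = 1 px), additive Gaussian noise (SD 0.05), clipped to [0, 1],
with ground-truth label movies emitted alongside.

Two properties of this world matter when interpreting green tests:

* **The recovered outline carries a sub-pixel halo.** Li's threshold on
  the 0.1/0.9 blurred map settles near 0.33, which places the recovered
  boundary about 0.5 px outside the true edge. This is a property of
  minimum-cross-entropy thresholding on this probability model, not a
  labeling defect, and it is resolution-dependent: the recovery
  benchmark therefore samples at 0.3 µm/px, where the halo costs a few
  percent of IoU, rather than at coarser scales where it dominates.
* **Fixed-area recovery needs full retraction.** With the single-cell
  defaults (L0 > A) each protrusion base is occupied in every frame and
  genuinely belongs to the fixed region — the true fixed area *exceeds*
  the core. The benchmark world for "fixed area recovers the core" uses
  fully retracting protrusions (L0 = A = 6 µm), so every protrusion
  pixel has occupancy below 97%.

What the generator does **not** emulate: imaging drift, uneven
illumination, depth-dependent blur, touching/overlapping cells in 3D,
cell-to-cell size heterogeneity within a condition, and protrusion
branching. A green recovery test therefore establishes that the labeling
machinery and feature estimators are correct on clean, well-separated
cells — not that segmentation of crowded, drifting tissue is solved.

## Numerical choices and conventions

* Coordinates are 0-based row-major in the compiled kernels and 1-based
  in R; areas are pixel counts × pixel size², lengths in µm.
* Radii in µm round to the nearest ≥ 1 px integer structuring element.
* Components and seeds use 8-connectivity (thin diagonal protrusions must
  stay connected); hole detection uses 4-connectivity on the complement.
* Occupancy and seed thresholds compare with a 1e-9 absolute tolerance.
* Watershed flooding breaks elevation ties FIFO; matching breaks distance
  ties by construction order — both deterministic.
* The DAC lag rounds to ≥ 1 frame; movies shorter than the lag are an
  error, not a silent skip.
* Cells with an empty frame, an empty fixed mask, or zero fixed area are
  excluded from summaries with a logged reason.
* Trend units are per second, so movies with different frame intervals
  are comparable.

## Known limitations

* The perimeter estimator suppresses structures thinner than ~2 px;
  measure at a resolution where protrusions are wider than that.
* Protrusiveness counts arcs on rasterized rings; at ring radii below
  ~8 px discretization can merge nearby arcs.
* The angularity operator is a single opening with a configurable disk;
  published erosion–dilation sequences vary and the disk radius is the
  tunable proxy (default 1.0 µm).
* Cells overlapping in the projection cannot be disentangled in 2D; the
  watershed will split them along the probability ridge, which may not
  be the biological boundary.
* The exact cross-match p-value is conservative for even, equal group
  sizes (see above); use `p_value_approx` when calibrated size matters.
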