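# morphodyn

Quantitative morphodynamics of sessile cells in 2D time-lapse microscopy.

Resident tissue macrophages and similar sessile immune cells stay anchored
in their niche and sample the surrounding interstitial space with membrane
protrusions that extend and retract over minutes. Their functional state
shows up in *how their shape changes over time*, not in displacement.
`morphodyn` is for experimentalists and image analysts who have 2D+T
movies of such cells (typically pixel-classifier probability maps,
projected from intravital two-photon stacks) and want reproducible,
interpretable numbers out of them.

The package implements the full chain:

1. **Segmentation & labeling** — per-frame Li minimum-cross-entropy
   thresholding, morphological cleanup (0.6 µm opening, 10 µm² hole/object
   filters), seed generation from the time-integrated movie (pixels
   occupied ≥ 97% of frames, components ≥ 50 µm²), and a two-pass seeded
   watershed (with a 2.2 µm diamond dilation pass that re-attaches
   protrusion fragments), plus file-driven curation (merge/exclude).
2. **Per-cell features** — for every frame: area, perimeter (sub-pixel
   iso-contour estimator), solidity, convexity, circularity
   (4πA/P²), aspect ratio, angularity, maximum protrusion length
   (directed Hausdorff distance from the cell boundary to the fixed-area
   outline), Sholl-style protrusiveness (arc counts on concentric 8 µm
   circles), and the dynamic area change
   DAC(t) = |mask(t) △ mask(t + 14 s)|.
3. **Summaries** — each cell becomes a vector of **31 quantifiers**: for
   nine per-frame series the mean, the mean-normalised SD and the OLS
   trend per second, plus fixed area, mean mobile area, mobile/fixed
   ratio, and the slope of the cumulative DAC sum.
4. **Population statistics** — two-sided permutation Welch tests per
   quantifier; the exact Rosenbaum cross-match test for comparing two
   populations as multivariate distributions (optimal non-bipartite
   minimum-distance matching under standardized Euclidean distance, with
   the closed-form null
   `P(A1 = a1) = 2^a1 (N/2)! / (C(N, m) a0! a1! a2!)`); and a PCA
   morphospace with loadings, scores and kernel densities.

A seeded synthetic-movie generator (elliptical core + capsule protrusions
with sinusoidal length laws, rasterized into noisy probability maps with
ground-truth labels) makes every stage testable without microscopy data.

The image primitives (multi-page TIFF I/O, connected components, binary
morphology, exact Euclidean distance transform, seeded watershed,
marching-squares contours) and the exact weighted blossom matching are
implemented in the package (C++ via Rcpp) and validated against
brute-force oracles in the test suite.

## Worked example

```r
library(morphodyn)

# A 3-cell synthetic tissue movie with known ground truth
prm    <- morphodyn:::default_tissue_params(seed = 3)
tissue <- do.call(simulate_tissue_movie, prm)

# Full pipeline: segment -> features -> 31 quantifiers per cell
out <- run_pipeline(tissue$prob_movie, "demo_out", condition = "ctrl")
out$population[, c("cell_id", "mean_area", "var_perimeter",
                   "ratio_mobile_fixed", "dac_cumsum_slope")]
#>    cell_id mean_area var_perimeter ratio_mobile_fixed dac_cumsum_slope
#> 1:       1  235.8147     0.2091892          0.5478097         3.050429
#> 2:       2  236.0993     0.1909399          0.5415653         3.092934
#> 3:       3  236.2751     0.1592996          0.5382216         3.085826
```

The three cells are simulated with identical geometry, and the pipeline
recovers nearly identical quantifiers: a mean area of ~236 µm², about 54%
as much mobile as fixed area (these cells retract their protrusions
fully), and a shape-turnover rate (cumulative DAC slope) of ~3.1 µm²/s.

Comparing two populations in the 31-dimensional quantifier space:

```r
pop <- simulate_feature_population(20, 20, dims = 31, shift = 3, seed = 1)
crossmatch_test(pop$A, pop$B)
#> Rosenbaum cross-match test: m = 20, n = 20
#>   pairs: 7 within-A, 6 cross, 7 within-B
#>   P(A1 <= 6) = 0.06927

w <- permutation_welch_test(pop$A[, 1], pop$B[, 1],
                            n_permutations = 10000, seed = 1)
sprintf("t = %.2f, p = %.4g", w$t_obs, w$p_value)
#> [1] "t = -0.90, p = 0.3733"
```

The populations differ by a Mahalanobis shift of 3 spread over 31
dimensions — far too small to see on any single quantifier (the Welch
test on quantifier 1 gives p = 0.37) — yet the multivariate cross-match
statistic already flags it: only 6 of 20 matched pairs join the groups,
with exact lower-tail p = 0.069. This is the argument for comparing cell
populations as whole distributions rather than marginal by marginal.

## Command line

```sh
Rscript inst/cli/morphodyn.R simulate --preset tissue --seed 3 --out sim/
Rscript inst/cli/morphodyn.R run sim/tissue_prob.tif out/ \
    --pixel-size-um 0.3 --frame-interval-s 14
Rscript inst/cli/morphodyn.R compare A_summary.csv B_summary.csv \
    --test crossmatch
```

Commands: `simulate`, `segment`, `features`, `summarize`, `compare`,
`morphospace`, `run`. Exit codes: 0 ok, 1 input error, 2 internal error.
Every `run` output directory contains a JSON manifest (config snapshot,
input hash, seed, per-stage object counts); a rerun with matching inputs
resumes from the existing outputs.

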