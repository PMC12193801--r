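#' Spatial and temporal calibration of a movie
#'
#' Every physical-unit parameter in the pipeline converts to pixels/frames
#' through a calibration object. The live-imaging pixel size is instrument
#' dependent and has no default: it must be supplied by the user.
#'
#' @param pixel_size_um length of one pixel side, in micrometres (> 0).
#' @param frame_interval_s time between consecutive frames, in seconds (> 0).
#' @return An object of class `morphodyn_calibration`.
#' @examples
#' cal <- calibration(pixel_size_um = 0.55, frame_interval_s = 14)
#' @export
calibration <- function(pixel_size_um, frame_interval_s) {
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1,
            is.finite(pixel_size_um), pixel_size_um > 0,
            is.numeric(frame_interval_s), length(frame_interval_s) == 1,
            is.finite(frame_interval_s), frame_interval_s > 0)
  structure(list(pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "morphodyn_calibration")
}

#' @export
print.morphodyn_calibration <- function(x, ...) {
  cat(sprintf("calibration: %g um/px, %g s/frame\n",
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Pipeline configuration
#'
#' Holds every tunable parameter of the segmentation, feature and statistics
#' stages. The defaults are the published values of the reference pipeline:
#' a 0.97 occupancy threshold for fixed/seed areas, a 0.6 um disk for binary
#' opening, 10 um^2 hole/object filters, a 50 um^2 seed size filter, a
#' 2.2 um diamond for the re-attachment dilation, 8 um Sholl radius steps,
#' a 14 s lag for the dynamic area change, and a 1.0 um disk for the
#' angularity opening.
#'
#' @param fixed_threshold fraction of frames a pixel must be occupied to
#'   count as fixed (in (0, 1]).
#' @param opening_radius_um radius of the disk used for binary opening (um).
#' @param min_hole_area_um2 holes smaller than this are filled (um^2).
#' @param min_object_area_um2 objects smaller than this are removed (um^2).
#' @param seed_min_area_um2 seed components smaller than this are dropped
#'   (um^2).
#' @param dilation_radius_um radius of the diamond structuring element used
#'   to re-attach detached protrusion fragments (um).
#' @param sholl_step_um radial spacing of the concentric Sholl circles (um).
#' @param dac_lag_s time lag of the dynamic area change (s).
#' @param angularity_radius_um radius of the disk whose opening defines
#'   angularity (um).
#' @param perimeter_sigma_px Gaussian smoothing (in pixels) applied to the
#'   mask before measuring the sub-pixel iso-contour perimeter; see the
#'   methods vignette for the calibration of this estimator.
#' @param n_permutations number of label permutations for the permutation
#'   Welch test.
#' @param rng_seed integer seed recorded with pipeline runs.
#' @param raw_sd if `TRUE`, report raw standard deviations instead of
#'   mean-normalised ones in the summary quantifiers.
#' @return An object of class `morphodyn_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$fixed_threshold
#' @export
pipeline_config <- function(fixed_threshold = 0.97,
                            opening_radius_um = 0.6,
                            min_hole_area_um2 = 10,
                            min_object_area_um2 = 10,
                            seed_min_area_um2 = 50,
                            dilation_radius_um = 2.2,
                            sholl_step_um = 8,
                            dac_lag_s = 14,
                            angularity_radius_um = 1.0,
                            perimeter_sigma_px = 1.0,
                            n_permutations = 10000,
                            rng_seed = 0L,
                            raw_sd = FALSE) {
  lens <- c(opening_radius_um = opening_radius_um,
            min_hole_area_um2 = min_hole_area_um2,
            min_object_area_um2 = min_object_area_um2,
            seed_min_area_um2 = seed_min_area_um2,
            dilation_radius_um = dilation_radius_um,
            sholl_step_um = sholl_step_um,
            dac_lag_s = dac_lag_s,
            angularity_radius_um = angularity_radius_um,
            perimeter_sigma_px = perimeter_sigma_px)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths, areas and lags must be strictly positive")
  if (!is.numeric(fixed_threshold) || fixed_threshold <= 0 ||
      fixed_threshold > 1)
    stop("fixed_threshold must lie in (0, 1]")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(fixed_threshold = fixed_threshold,
                 opening_radius_um = opening_radius_um,
                 min_hole_area_um2 = min_hole_area_um2,
                 min_object_area_um2 = min_object_area_um2,
                 seed_min_area_um2 = seed_min_area_um2,
                 dilation_radius_um = dilation_radius_um,
                 sholl_step_um = sholl_step_um,
                 dac_lag_s = dac_lag_s,
                 angularity_radius_um = angularity_radius_um,
                 perimeter_sigma_px = perimeter_sigma_px,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed),
                 raw_sd = isTRUE(raw_sd)),
            class = "morphodyn_config")
}

# Radii given in um are rounded to the nearest >= 1 pixel integer.
um_to_px <- function(r_um, cal) {
  max(1L, as.integer(round(r_um / cal$pixel_size_um)))
}

px_area_um2 <- function(cal) cal$pixel_size_um^2

# Structuring element offsets (dy, dx) for a disk of radius r pixels.
disk_offsets <- function(r_px) {
  d <- seq(-r_px, r_px)
  g <- expand.grid(dy = d, dx = d)
  g <- g[g$dy^2 + g$dx^2 <= r_px^2 + 1e-9, ]
  as.matrix(g)
}

# Diamond (L1 ball) of radius r pixels.
diamond_offsets <- function(r_px) {
  d <- seq(-r_px, r_px)
  g <- expand.grid(dy = d, dx = d)
  g <- g[abs(g$dy) + abs(g$dx) <= r_px, ]
  as.matrix(g)
}
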