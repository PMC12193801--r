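# Per-frame and per-movie size/shape/dynamics features for one cell.

# --- perimeter estimator -----------------------------------------------------
#
# Perimeter of a binary mask, measured as the length of the 0.5 iso-contour
# of the Gaussian-smoothed mask (marching squares with linear
# interpolation). Smoothing removes the rasterization staircase that makes
# pixel-edge counting overestimate smooth outlines by up to 4/pi, while the
# 0.5 level keeps straight edges at their true position; see the methods
# vignette for the calibration on analytic shapes. sigma is in pixels;
# structures thinner than ~2 px may fall below the 0.5 level and vanish.
mask_perimeter_px <- function(mask, sigma_px = 1.0) {
  if (!any(mask)) return(0)
  pad <- as.integer(ceiling(3 * sigma_px) + 2)
  ny <- nrow(mask); nx <- ncol(mask)
  f <- matrix(0, ny + 2 * pad, nx + 2 * pad)
  f[(pad + 1):(pad + ny), (pad + 1):(pad + nx)] <- mask * 1
  k <- seq(-ceiling(3 * sigma_px), ceiling(3 * sigma_px))
  kern <- exp(-k^2 / (2 * sigma_px^2))
  kern <- kern / sum(kern)
  cpp_contour_length(cpp_sepconv(f, kern), 0.5)
}

# --- convex hull -------------------------------------------------------------

# Convex hull polygon over the pixel *corners* of the mask (so every pixel
# square is contained in the hull). Returns a closed polygon as an (x, y)
# matrix in pixel coordinates (pixel centres at integers).
hull_polygon <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  px <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  py <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- chull(px, py)
  cbind(x = px[h], y = py[h])
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Rasterize a convex polygon onto the mask grid (pixel centres inside or on
# the polygon). Even-odd rule with a half-open tolerance on edges.
rasterize_polygon <- function(poly, ny, nx) {
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  px <- g$x; py <- g$y
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  matrix(inside, ny, nx)
}

# --- frame features ----------------------------------------------------------

#' Size and shape features of one binary frame
#'
#' Computes: area (pixel count times pixel area), perimeter (sub-pixel
#' iso-contour estimator), solidity (area / convex hull area), convexity
#' (hull perimeter / perimeter, same estimator applied to the rasterized
#' hull, clipped to at most 1), circularity (`4*pi*A/P^2`, clipped to at
#' most 1), aspect ratio (minor/major axis of the inertia-equivalent
#' ellipse) and angularity (relative area lost by opening with a disk of
#' `angularity_radius_um`).
#'
#' @param mask non-empty logical or 0/1 matrix.
#' @param calibration a [calibration()].
#' @param config a [pipeline_config()].
#' @return Named list: `area_um2`, `perimeter_um`, `solidity`, `convexity`,
#'   `circularity`, `aspect_ratio`, `angularity`.
#' @export
frame_shape_features <- function(mask, calibration, config = pipeline_config()) {
  m <- mask > 0
  if (!any(m)) stop("frame_shape_features: empty mask (features undefined)")
  px <- calibration$pixel_size_um
  npix <- sum(m)
  area <- npix * px^2
  P_px <- mask_perimeter_px(m, config$perimeter_sigma_px)
  perimeter <- P_px * px

  hull <- hull_polygon(m)
  hull_area <- polygon_area(hull)
  solidity <- min(1, npix / hull_area)
  hull_mask <- rasterize_polygon(hull, nrow(m), ncol(m)) | m
  Ph_px <- if (identical(hull_mask, m)) P_px
           else mask_perimeter_px(hull_mask, config$perimeter_sigma_px)
  convexity <- if (P_px > 0) min(1, Ph_px / P_px) else NA_real_
  circularity <- if (P_px > 0) min(1, 4 * pi * npix / P_px^2) else NA_real_

  idx <- which(m, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  # Second central moments with the 1/12 pixel-extent correction.
  dy <- idx[, 1] - cy; dx <- idx[, 2] - cx
  cov <- matrix(c(mean(dx^2) + 1 / 12, mean(dx * dy),
                  mean(dx * dy), mean(dy^2) + 1 / 12), 2, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  aspect_ratio <- sqrt(max(0, ev[2]) / ev[1])

  se <- disk_offsets(um_to_px(config$angularity_radius_um, calibration))
  opened <- cpp_binary_morph(cpp_binary_morph(m, se, FALSE), se, TRUE)
  angularity <- min(1, max(0, (npix - sum(opened)) / npix))

  list(area_um2 = area, perimeter_um = perimeter, solidity = solidity,
       convexity = convexity, circularity = circularity,
       aspect_ratio = aspect_ratio, angularity = angularity)
}

# --- fixed and mobile area ---------------------------------------------------

#' Fixed and mobile area of a cell movie
#'
#' The fixed mask consists of the pixels whose temporal mean occupancy is
#' at least `fixed_threshold`; the mobile area per frame is the cell area
#' outside the fixed mask.
#'
#' @param cm a [cell_movie()] with at least 2 frames.
#' @param config a [pipeline_config()].
#' @return An object of class `morphodyn_fixed_mobile`: list with
#'   `fixed_mask`, `fixed_area_um2`, `mobile_area_um2` (per frame) and
#'   `flagged` (TRUE when the fixed mask is empty).
#' @export
fixed_mobile <- function(cm, config = pipeline_config()) {
  stopifnot(inherits(cm, "morphodyn_movie"))
  if (n_frames(cm) < 2) stop("fixed_mobile requires at least 2 frames")
  cal <- movie_cal(cm)
  occ <- apply(cm > 0, c(1, 2), mean)
  fixed <- occ >= config$fixed_threshold - 1e-9
  px2 <- px_area_um2(cal)
  fixed_area <- sum(fixed) * px2
  mobile <- vapply(seq_len(n_frames(cm)), function(t) {
    m <- get_mask(cm, t)
    (sum(m) - sum(m & fixed)) * px2
  }, numeric(1))
  flagged <- !any(fixed)
  if (flagged)
    md_log("features", "cell %s: empty fixed mask, protrusion features undefined",
           attr(cm, "cell_id") %||% "?")
  structure(list(fixed_mask = fixed, fixed_area_um2 = fixed_area,
                 mobile_area_um2 = mobile, flagged = flagged),
            class = "morphodyn_fixed_mobile")
}

# --- protrusion features -----------------------------------------------------

#' Maximum protrusion length
#'
#' Directed Hausdorff distance from the cell boundary to the fixed-area
#' outline: the maximum over cell boundary pixels of the Euclidean distance
#' to the nearest fixed-outline pixel, in micrometres. Unsigned: a cell
#' shrunk inside its fixed mask also yields a positive distance.
#'
#' @param mask non-empty cell mask.
#' @param fixed_mask non-empty fixed-area mask.
#' @param calibration a [calibration()].
#' @return Length in um.
#' @export
max_protrusion_length <- function(mask, fixed_mask, calibration) {
  m <- mask > 0; fx <- fixed_mask > 0
  if (!any(m) || !any(fx))
    stop("max_protrusion_length: empty mask (undefined)")
  cell_b <- cpp_boundary(m)
  fixed_b <- cpp_boundary(fx)
  d <- cpp_edt(fixed_b)
  max(d[cell_b]) * calibration$pixel_size_um
}

# Ring pixels of a circle of radius r_px around (cy, cx), ordered by angle
# (8-connected rasterization via dense angular sampling).
ring_pixels <- function(cy, cx, r_px, ny, nx) {
  ntheta <- max(64, ceiling(2 * pi * r_px / 0.2))
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  y <- round(cy + r_px * sin(th))
  x <- round(cx + r_px * cos(th))
  keep <- c(TRUE, diff(y) != 0 | diff(x) != 0)
  y <- y[keep]; x <- x[keep]
  if (length(y) > 1 && y[1] == y[length(y)] && x[1] == x[length(x)]) {
    y <- y[-length(y)]; x <- x[-length(x)]
  }
  cbind(y = y, x = x)
}

# Count connected arcs (cyclic runs of mask membership) on one ring.
ring_arc_count <- function(mask, ring) {
  ny <- nrow(mask); nx <- ncol(mask)
  ok <- ring[, 1] >= 1 & ring[, 1] <= ny & ring[, 2] >= 1 & ring[, 2] <= nx
  inmask <- logical(nrow(ring))
  inmask[ok] <- mask[cbind(ring[ok, 1], ring[ok, 2])]
  if (!any(inmask)) return(0L)
  if (all(inmask)) return(1L)
  starts <- sum(inmask & !c(inmask[length(inmask)], inmask[-length(inmask)]))
  as.integer(starts)
}

#' Protrusiveness (Sholl-style arc count)
#'
#' Concentric circles with radii in multiples of `sholl_step_um` are drawn
#' around the centroid of the fixed mask, up to the maximum radial extent
#' of the cell; for each circle the number of connected arcs where it
#' intersects the cell body is counted (with angular wraparound), and the
#' counts are summed over circles.
#'
#' @param mask non-empty cell mask.
#' @param fixed_mask non-empty fixed-area mask (its centroid is the Sholl
#'   centre).
#' @param calibration a [calibration()].
#' @param config a [pipeline_config()].
#' @return Integer arc count (0 if the cell does not reach the first
#'   circle).
#' @export
protrusiveness <- function(mask, fixed_mask, calibration,
                           config = pipeline_config()) {
  m <- mask > 0; fx <- fixed_mask > 0
  if (!any(m) || !any(fx)) stop("protrusiveness: empty mask (undefined)")
  idx <- which(fx, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  px <- calibration$pixel_size_um
  midx <- which(m, arr.ind = TRUE)
  max_r_um <- max(sqrt((midx[, 1] - cy)^2 + (midx[, 2] - cx)^2)) * px
  if (max_r_um < config$sholl_step_um) return(0L)
  radii <- seq(config$sholl_step_um, max_r_um, by = config$sholl_step_um)
  total <- 0L
  for (r in radii) {
    ring <- ring_pixels(cy, cx, r / px, nrow(m), ncol(m))
    total <- total + ring_arc_count(m, ring)
  }
  total
}

# --- dynamic area change -----------------------------------------------------

#' Dynamic area change (DAC) series
#'
#' `DAC(t)` is the area of the symmetric difference between the cell masks
#' at frames `t` and `t + lag`, where the lag is `dac_lag_s` rounded to the
#' nearest frame count (minimum 1).
#'
#' @param cm a [cell_movie()].
#' @param config a [pipeline_config()].
#' @return Numeric vector of length `T - lag` (um^2), with attributes
#'   `lag_frames` and `lag_s` (the actual lag used).
#' @export
dynamic_area_change <- function(cm, config = pipeline_config()) {
  stopifnot(inherits(cm, "morphodyn_movie"))
  cal <- movie_cal(cm)
  lag <- max(1L, as.integer(round(config$dac_lag_s / cal$frame_interval_s)))
  T_ <- n_frames(cm)
  if (T_ <= lag)
    stop(sprintf("movie too short for DAC: %d frame(s) <= lag of %d", T_, lag))
  px2 <- px_area_um2(cal)
  dac <- vapply(seq_len(T_ - lag), function(t) {
    sum(xor(get_mask(cm, t), get_mask(cm, t + lag))) * px2
  }, numeric(1))
  structure(dac, lag_frames = lag, lag_s = lag * cal$frame_interval_s)
}

# --- assembled time series ---------------------------------------------------

#' Full feature time series of one cell
#'
#' Assembles all per-frame shape features, the fixed/mobile decomposition,
#' protrusion features and the DAC series with time stamps. A cell with
#' any empty frame is marked unusable (`usable = FALSE`) and its per-frame
#' features are `NA` in those frames.
#'
#' @param cm a [cell_movie()] with at least 2 frames.
#' @param config a [pipeline_config()].
#' @return An object of class `morphodyn_timeseries`: list with `frames`
#'   (a data.table, one row per frame), `fixed` (the [fixed_mobile()]
#'   result), `dac`, `cell_id`, `usable` and `calibration`.
#' @export
feature_timeseries <- function(cm, config = pipeline_config()) {
  stopifnot(inherits(cm, "morphodyn_movie"))
  T_ <- n_frames(cm)
  if (T_ < 2) stop("feature_timeseries requires at least 2 frames")
  cal <- movie_cal(cm)
  cell_id <- attr(cm, "cell_id") %||% 1L
  empty <- vapply(seq_len(T_), function(t) !any(cm[, , t] > 0), logical(1))
  fm <- fixed_mobile(cm, config)
  usable <- !any(empty) && !fm$flagged
  rows <- lapply(seq_len(T_), function(t) {
    if (empty[t])
      return(data.table::data.table(
        frame = t, time_s = (t - 1) * cal$frame_interval_s,
        area_um2 = NA_real_, perimeter_um = NA_real_, solidity = NA_real_,
        convexity = NA_real_, circularity = NA_real_,
        aspect_ratio = NA_real_, angularity = NA_real_,
        max_protrusion_um = NA_real_, protrusiveness = NA_real_,
        mobile_area_um2 = NA_real_))
    m <- get_mask(cm, t)
    fs <- frame_shape_features(m, cal, config)
    prot_len <- if (fm$flagged) NA_real_
                else max_protrusion_length(m, fm$fixed_mask, cal)
    prot_cnt <- if (fm$flagged) NA_real_
                else as.numeric(protrusiveness(m, fm$fixed_mask, cal, config))
    data.table::data.table(
      frame = t, time_s = (t - 1) * cal$frame_interval_s,
      area_um2 = fs$area_um2, perimeter_um = fs$perimeter_um,
      solidity = fs$solidity, convexity = fs$convexity,
      circularity = fs$circularity, aspect_ratio = fs$aspect_ratio,
      angularity = fs$angularity, max_protrusion_um = prot_len,
      protrusiveness = prot_cnt, mobile_area_um2 = fm$mobile_area_um2[t])
  })
  dac <- if (!any(empty)) dynamic_area_change(cm, config) else NULL
  structure(list(frames = data.table::rbindlist(rows), fixed = fm,
                 dac = dac, cell_id = cell_id, usable = usable,
                 calibration = cal),
            class = "morphodyn_timeseries")
}
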