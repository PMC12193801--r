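# Ground-truthed synthetic data: single-cell movies, multi-cell tissue
# movies with probability-map noise, and multivariate feature populations.
#
# The generated cell emulates a sessile tissue macrophage: a temporally
# fixed elliptical core with K capsule-shaped protrusions whose lengths
# oscillate quasi-periodically, L_k(t) = L0 + A sin(2 pi t / T_p + phi_k).

#' Parameters of one synthetic cell
#'
#' Defaults describe a plausible sessile-macrophage geometry at typical
#' two-photon live-imaging scale: 0.55 um pixels, one frame every 14 s,
#' a 10-minute movie, an 8 x 6 um core, and 5 protrusions of resting
#' length 8 um oscillating by 4 um with a 2-minute period (simulator
#' defaults, not measured values).
#'
#' @param pixel_size_um,frame_interval_s calibration of the rasterized
#'   movie.
#' @param duration_s movie length in seconds.
#' @param core_semi_axes_um ellipse semi-axes (a, b) of the fixed core.
#' @param core_center_um cell centre in physical coordinates; defaults to
#'   the frame centre.
#' @param n_protrusions number of protrusions K.
#' @param protrusion_width_um full width of each capsule-shaped protrusion.
#' @param protrusion_l0_um resting protrusion length L0 (beyond the core
#'   boundary).
#' @param protrusion_amplitude_um oscillation amplitude A (requires
#'   `L0 - A >= 0`).
#' @param protrusion_period_s oscillation period T_p.
#' @param angles_deg optional protrusion directions; defaults to even
#'   spacing with seeded jitter.
#' @param phases optional oscillation phases; defaults to seeded uniform
#'   draws.
#' @param frame_size_um optional square frame side; computed from the
#'   geometry when omitted.
#' @param seed integer RNG seed.
#' @return An object of class `morphodyn_cell_params`.
#' @export
synthetic_cell_params <- function(pixel_size_um = 0.55,
                                  frame_interval_s = 14,
                                  duration_s = 600,
                                  core_semi_axes_um = c(8, 6),
                                  core_center_um = NULL,
                                  n_protrusions = 5,
                                  protrusion_width_um = 2.5,
                                  protrusion_l0_um = 8,
                                  protrusion_amplitude_um = 4,
                                  protrusion_period_s = 120,
                                  angles_deg = NULL,
                                  phases = NULL,
                                  frame_size_um = NULL,
                                  seed = 1L) {
  if (protrusion_l0_um - protrusion_amplitude_um < 0)
    stop("protrusion length law must stay non-negative: require L0 - A >= 0")
  if (n_protrusions < 0) stop("n_protrusions must be >= 0")
  stopifnot(all(core_semi_axes_um > 0), protrusion_width_um > 0,
            protrusion_period_s > 0, duration_s > 0)
  K <- as.integer(n_protrusions)
  rand <- with_seed(as.integer(seed), list(
    jitter = stats::runif(max(K, 1), -10, 10),
    phases = stats::runif(max(K, 1), 0, 2 * pi)))
  if (is.null(angles_deg) && K > 0)
    angles_deg <- seq(0, 360, length.out = K + 1)[seq_len(K)] +
      rand$jitter[seq_len(K)]
  if (is.null(phases) && K > 0) phases <- rand$phases[seq_len(K)]
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 duration_s = duration_s,
                 core_semi_axes_um = core_semi_axes_um,
                 core_center_um = core_center_um,
                 n_protrusions = K,
                 protrusion_width_um = protrusion_width_um,
                 protrusion_l0_um = protrusion_l0_um,
                 protrusion_amplitude_um = protrusion_amplitude_um,
                 protrusion_period_s = protrusion_period_s,
                 angles_deg = angles_deg, phases = phases,
                 frame_size_um = frame_size_um, seed = as.integer(seed)),
            class = "morphodyn_cell_params")
}

# Protrusion lengths at time t (vector over protrusions).
protrusion_lengths <- function(p, t_s) {
  if (p$n_protrusions == 0) return(numeric(0))
  p$protrusion_l0_um + p$protrusion_amplitude_um *
    sin(2 * pi * t_s / p$protrusion_period_s + p$phases)
}

# Radius of the core ellipse along direction theta (radians).
ellipse_radius <- function(a, b, theta) {
  1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
}

rasterize_cell_frame <- function(p, t_s, X, Y) {
  # X, Y: physical coordinates (um) of pixel centres.
  ctr <- p$core_center_um
  a <- p$core_semi_axes_um[1]; b <- p$core_semi_axes_um[2]
  m <- ((X - ctr[1]) / a)^2 + ((Y - ctr[2]) / b)^2 <= 1
  if (p$n_protrusions > 0) {
    th <- p$angles_deg * pi / 180
    L <- protrusion_lengths(p, t_s)
    r0 <- ellipse_radius(a, b, th)
    hw <- p$protrusion_width_um / 2
    for (k in seq_len(p$n_protrusions)) {
      if (L[k] <= 0) next
      ux <- cos(th[k]); uy <- sin(th[k])
      # The capsule axis starts half a width *inside* the core boundary, so
      # the rounded tip reaches exactly r0 + L and the lobe retracts fully
      # into the core as L -> 0.
      sx <- ctr[1] + (r0[k] - hw) * ux; sy <- ctr[2] + (r0[k] - hw) * uy
      proj <- pmin(pmax((X - sx) * ux + (Y - sy) * uy, 0), L[k])
      d2 <- (X - sx - proj * ux)^2 + (Y - sy - proj * uy)^2
      m <- m | (d2 <= hw^2)
    }
  }
  m
}

#' Simulate one cell movie with analytic ground truth
#'
#' @param params a [synthetic_cell_params()] object.
#' @return List with `movie` (a binary [cell_movie()]) and `truth`: the
#'   rasterized `core_mask`, the analytic `expected_area_um2` per frame
#'   (core plus capsule lobes, ignoring sub-pixel base overlap), protrusion
#'   `tips_um` per frame, and the parameters. Deterministic given
#'   `params$seed`.
#' @export
simulate_cell_movie <- function(params) {
  stopifnot(inherits(params, "morphodyn_cell_params"))
  p <- params
  a <- p$core_semi_axes_um[1]; b <- p$core_semi_axes_um[2]
  reach <- max(a, b) +
    (if (p$n_protrusions > 0)
       p$protrusion_l0_um + p$protrusion_amplitude_um +
         p$protrusion_width_um / 2 else 0)
  need <- 2 * (reach + 2)
  if (is.null(p$frame_size_um)) p$frame_size_um <- need
  npix <- ceiling(p$frame_size_um / p$pixel_size_um)
  if (is.null(p$core_center_um))
    p$core_center_um <- rep(p$frame_size_um / 2, 2)
  if (any(p$core_center_um - reach < 0) ||
      any(p$core_center_um + reach > p$frame_size_um))
    stop(sprintf("cell geometry exceeds the frame; use frame_size_um >= %.1f",
                 need))
  coord <- (seq_len(npix) - 1) * p$pixel_size_um
  X <- matrix(coord, npix, npix, byrow = TRUE)  # x varies along columns
  Y <- matrix(coord, npix, npix)
  times <- seq(0, p$duration_s, by = p$frame_interval_s)
  frames <- lapply(times, function(t_s)
    rasterize_cell_frame(p, t_s, X, Y) * 1L)
  core <- ((X - p$core_center_um[1]) / a)^2 +
    ((Y - p$core_center_um[2]) / b)^2 <= 1
  hw <- p$protrusion_width_um / 2
  # Lobe area beyond the (locally flat) core boundary: for L >= w/2 a
  # w x (L - w/2) bar plus the forward half-cap; for shorter lobes only a
  # circular segment of the tip cap protrudes. Curvature of the core
  # boundary is neglected (O(w^3/R) at these scales).
  lobe_area <- function(L) {
    vapply(L, function(l) {
      if (l <= 0) return(0)
      if (l >= hw)
        return(p$protrusion_width_um * (l - hw) + pi * hw^2 / 2)
      d <- hw - l # distance from tip-cap centre to the boundary line
      hw^2 * acos(d / hw) - d * sqrt(hw^2 - d^2)
    }, numeric(1))
  }
  expected_area <- vapply(times, function(t_s) {
    pi * a * b + sum(lobe_area(protrusion_lengths(p, t_s)))
  }, numeric(1))
  tips <- lapply(times, function(t_s) {
    if (p$n_protrusions == 0) return(matrix(numeric(0), 0, 2))
    th <- p$angles_deg * pi / 180
    r <- ellipse_radius(a, b, th) + protrusion_lengths(p, t_s)
    cbind(x = p$core_center_um[1] + r * cos(th),
          y = p$core_center_um[2] + r * sin(th))
  })
  cal <- calibration(p$pixel_size_um, p$frame_interval_s)
  list(movie = cell_movie(frames, cal, cell_id = 1L),
       truth = list(core_mask = core, expected_area_um2 = expected_area,
                    tips_um = tips, times_s = times, params = p))
}

#' Simulate a multi-cell tissue movie as a noisy probability map
#'
#' Cells are rasterized on one shared canvas; the union becomes foreground
#' probability `p_fg`, the background `p_bg`; the map is blurred with a
#' Gaussian and corrupted with additive noise, then clipped to \[0, 1\].
#' Overlapping cores are an error; ground-truth labels are emitted
#' alongside.
#'
#' @param cell_params list of [synthetic_cell_params()] objects, each with
#'   `core_center_um` set on the shared canvas.
#' @param frame_size_um side of the square canvas (um).
#' @param p_fg,p_bg foreground/background probability levels.
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = none).
#' @param noise_sd SD of additive Gaussian noise (0 = none).
#' @param seed integer seed for the noise.
#' @return List with `prob_movie`, ground-truth `labels` movie,
#'   `cell_movies` and `truths` (per-cell ground truth).
#' @export
simulate_tissue_movie <- function(cell_params, frame_size_um,
                                  p_fg = 0.9, p_bg = 0.1,
                                  blur_sigma_px = 1, noise_sd = 0.05,
                                  seed = 1L) {
  stopifnot(length(cell_params) >= 1)
  sims <- lapply(cell_params, function(cp) {
    stopifnot(inherits(cp, "morphodyn_cell_params"))
    if (is.null(cp$core_center_um))
      stop("tissue cells need explicit core_center_um placements")
    cp$frame_size_um <- frame_size_um
    simulate_cell_movie(cp)
  })
  cores <- lapply(sims, function(s) s$truth$core_mask)
  for (i in seq_along(cores))
    for (j in seq_len(i - 1))
      if (any(cores[[i]] & cores[[j]]))
        stop(sprintf("cores of cells %d and %d overlap", j, i))
  cal <- movie_cal(sims[[1]]$movie)
  T_ <- n_frames(sims[[1]]$movie)
  labels <- lapply(seq_len(T_), function(t) {
    lab <- matrix(0L, dim(sims[[1]]$movie)[1], dim(sims[[1]]$movie)[2])
    for (i in seq_along(sims)) {
      m <- get_mask(sims[[i]]$movie, t)
      lab[m & lab == 0L] <- i
    }
    lab
  })
  kern <- NULL
  if (blur_sigma_px > 0) {
    kk <- seq(-ceiling(3 * blur_sigma_px), ceiling(3 * blur_sigma_px))
    kern <- exp(-kk^2 / (2 * blur_sigma_px^2))
    kern <- kern / sum(kern)
  }
  prob <- with_seed(as.integer(seed), lapply(seq_len(T_), function(t) {
    f <- p_bg + (p_fg - p_bg) * (labels[[t]] > 0)
    if (!is.null(kern)) f <- cpp_sepconv(f, kern)
    if (noise_sd > 0) f <- f + matrix(stats::rnorm(length(f), 0, noise_sd),
                                      nrow(f), ncol(f))
    pmin(pmax(f, 0), 1)
  }))
  list(prob_movie = movie(prob, cal, kind = "probability"),
       labels = movie(labels, cal, kind = "labels"),
       cell_movies = lapply(seq_along(sims), function(i) {
         cm <- sims[[i]]$movie
         attr(cm, "cell_id") <- i
         cm
       }),
       truths = lapply(sims, `[[`, "truth"))
}

#' Simulate two multivariate-normal feature populations
#'
#' `A ~ N(0, Sigma)` and `B ~ N(delta, Sigma)`, where `delta` has
#' Mahalanobis length `shift` (spread evenly over dimensions).
#'
#' @param m,n sample sizes.
#' @param dims dimensionality.
#' @param shift Mahalanobis distance between the population means.
#' @param covariance optional positive-definite covariance (identity by
#'   default).
#' @param seed integer seed.
#' @return List with matrices `A` (m x dims) and `B` (n x dims) and the
#'   mean shift vector `delta`.
#' @export
simulate_feature_population <- function(m, n, dims = 31, shift = 0,
                                        covariance = NULL, seed = 1L) {
  stopifnot(m >= 1, n >= 1, dims >= 1)
  if (is.null(covariance)) covariance <- diag(dims)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == dims))
    stop("covariance must be dims x dims")
  R <- tryCatch(chol(covariance),
                error = function(e) stop("covariance is not positive definite"))
  u <- rep(1 / sqrt(dims), dims)
  delta <- as.numeric(shift * t(R) %*% u)
  with_seed(as.integer(seed), {
    A <- matrix(stats::rnorm(m * dims), m) %*% R
    B <- matrix(stats::rnorm(n * dims), n) %*% R +
      matrix(delta, n, dims, byrow = TRUE)
    list(A = A, B = B, delta = delta)
  })
}
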