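# Segmentation and labeling: probability-map movie -> per-cell binary movies.

#' Li minimum cross-entropy threshold
#'
#' Iterative fixed-point scheme: starting from the sample mean, the
#' threshold is repeatedly replaced by
#' `(mu_fg - mu_bg) / (log(mu_fg) - log(mu_bg))`, where `mu_bg`/`mu_fg` are
#' the means of values below/above the current threshold. The fixed point
#' minimises the cross entropy between the image and its binary
#' segmentation. Non-positive inputs are handled by shifting values into
#' the positive range for the iteration only.
#'
#' @param values numeric vector (or matrix) of pixel values.
#' @param tol convergence tolerance relative to the value range.
#' @return The threshold, or `NA_real_` for (near-)constant input.
#' @export
li_threshold <- function(values, tol = 1e-7) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(NA_real_)
  shift <- if (rng[1] <= 0) -rng[1] + 1e-6 * diff(rng) else 0
  v <- v + shift
  t_cur <- mean(v)
  for (i in 1:200) {
    lo <- v[v < t_cur]; hi <- v[v >= t_cur]
    if (!length(lo) || !length(hi)) break
    m0 <- mean(lo); m1 <- mean(hi)
    t_new <- (m1 - m0) / (log(m1) - log(m0))
    if (!is.finite(t_new)) break
    if (abs(t_new - t_cur) < tol * diff(rng)) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur - shift
}

#' Binarize a probability-map movie
#'
#' Thresholds each frame (or, with `global = TRUE`, the pooled movie) by
#' Li's iterative minimum cross-entropy method; foreground are values at or
#' above the threshold. Constant frames have no threshold: they are
#' returned empty with a warning.
#'
#' @param prob_movie a [movie()] of kind `"probability"` or `"intensity"`.
#' @param global pool all frames into one threshold (useful for movies with
#'   flickering exposure).
#' @return A binary [movie()].
#' @export
binarize_movie <- function(prob_movie, global = FALSE) {
  stopifnot(inherits(prob_movie, "morphodyn_movie"))
  T_ <- n_frames(prob_movie)
  thr_global <- if (global) li_threshold(prob_movie) else NA_real_
  out <- vector("list", T_)
  n_const <- 0
  for (t in seq_len(T_)) {
    f <- get_frame(prob_movie, t)
    thr <- if (global) thr_global else li_threshold(f)
    if (is.na(thr)) {
      out[[t]] <- matrix(0L, nrow(f), ncol(f))
      n_const <- n_const + 1
    } else {
      out[[t]] <- (f >= thr) * 1L
    }
  }
  if (n_const > 0)
    warning(sprintf("%d constant frame(s) had no threshold and were returned empty",
                    n_const))
  md_log("binarize", "thresholded %d frames (%d constant)", T_, n_const)
  movie(out, movie_cal(prob_movie), kind = "binary")
}

#' Clean one binary frame
#'
#' Morphological opening with a disk of radius `opening_radius_um`, then
#' filling of holes smaller than `min_hole_area_um2`, then removal of
#' foreground objects smaller than `min_object_area_um2`. Idempotent.
#'
#' @param mask logical or 0/1 matrix.
#' @param config a [pipeline_config()].
#' @param calibration a [calibration()].
#' @return A logical matrix.
#' @export
clean_binary_frame <- function(mask, config, calibration) {
  m <- mask > 0
  se <- disk_offsets(um_to_px(config$opening_radius_um, calibration))
  m <- cpp_binary_morph(cpp_binary_morph(m, se, FALSE), se, TRUE)
  px2 <- px_area_um2(calibration)
  # Fill small holes: background components (4-connected complement of the
  # 8-connected foreground) that do not touch the border.
  bg <- cpp_label_components(!m, 4L)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  tab <- tabulate(bg)
  hole_ids <- which(tab * px2 < config$min_hole_area_um2)
  hole_ids <- setdiff(hole_ids, border_ids)
  if (length(hole_ids)) m[bg %in% hole_ids] <- TRUE
  # Remove small objects.
  fg <- cpp_label_components(m, 8L)
  tab <- tabulate(fg)
  small <- which(tab * px2 < config$min_object_area_um2)
  if (length(small)) m[fg %in% small] <- FALSE
  m
}

# Clean every frame of a binary movie.
clean_binary_movie <- function(bin_movie, config) {
  cal <- movie_cal(bin_movie)
  frames <- lapply(seq_len(n_frames(bin_movie)), function(t) {
    clean_binary_frame(get_mask(bin_movie, t), config, cal) * 1L
  })
  movie(frames, cal, kind = "binary")
}

#' Seed labels from the time-integrated movie
#'
#' Pixels occupied in at least a fraction `fixed_threshold` of the frames
#' form the seed mask; connected components smaller than
#' `seed_min_area_um2` are removed and the rest labeled 1..K.
#'
#' @param binary_movie a cleaned binary [movie()].
#' @param config a [pipeline_config()].
#' @return An object of class `morphodyn_seeds`: list with `labels` (2D
#'   integer matrix) and `areas_um2` (per-label areas).
#' @export
seed_labels <- function(binary_movie, config) {
  stopifnot(inherits(binary_movie, "morphodyn_movie"))
  cal <- movie_cal(binary_movie)
  occ <- apply(binary_movie > 0, c(1, 2), mean)
  seed_mask <- occ >= config$fixed_threshold - 1e-9
  lab <- cpp_label_components(seed_mask, 8L)
  px2 <- px_area_um2(cal)
  tab <- tabulate(lab)
  keep <- which(tab * px2 >= config$seed_min_area_um2)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  if (!length(keep))
    warning("empty seed mask: no cells will be labeled")
  md_log("seeds", "%d seed component(s) kept, %d removed by size filter",
         length(keep), length(tab) - length(keep))
  structure(list(labels = lab,
                 areas_um2 = tabulate(lab, nbins = length(keep)) * px2,
                 calibration = cal),
            class = "morphodyn_seeds")
}

# Elevation surface for the watershed: negated probability map when
# available, else the negated distance-to-background transform.
ws_elevation <- function(domain_mask, prob_frame) {
  if (!is.null(prob_frame)) return(-prob_frame)
  d <- cpp_edt(!domain_mask)
  d[!is.finite(d)] <- 0
  -d
}

#' Label cells in every frame by two-pass seeded watershed
#'
#' Per frame: (i) watershed of the binary foreground from the seed labels;
#' (ii) dilation of the binary frame with a diamond of radius
#' `dilation_radius_um` and a second watershed seeded with the labels of
#' (i), which re-attaches protrusion fragments disconnected by
#' binarization; (iii) intersection of the result with the original binary
#' frame. Foreground not connected to any seed after dilation stays 0.
#'
#' @param binary_movie a cleaned binary [movie()].
#' @param seeds a [seed_labels()] result.
#' @param config a [pipeline_config()].
#' @param prob_movie optional probability [movie()] used as watershed
#'   elevation; the distance transform is used when absent.
#' @return A label [movie()].
#' @export
label_cells <- function(binary_movie, seeds, config, prob_movie = NULL) {
  stopifnot(inherits(binary_movie, "morphodyn_movie"),
            inherits(seeds, "morphodyn_seeds"))
  if (!all(dim(seeds$labels) == dim(binary_movie)[1:2]))
    stop("seed/movie shape mismatch")
  cal <- movie_cal(binary_movie)
  se <- diamond_offsets(um_to_px(config$dilation_radius_um, cal))
  T_ <- n_frames(binary_movie)
  out <- vector("list", T_)
  n_orphan <- 0
  for (t in seq_len(T_)) {
    m <- get_mask(binary_movie, t)
    pf <- if (is.null(prob_movie)) NULL else get_frame(prob_movie, t)
    lab1 <- cpp_watershed(ws_elevation(m, pf), seeds$labels, m)
    dil <- cpp_binary_morph(m, se, TRUE)
    lab2 <- cpp_watershed(ws_elevation(dil, pf), lab1, dil)
    final <- lab2 * m
    n_orphan <- n_orphan + sum(final == 0 & m)
    out[[t]] <- final
  }
  md_log("label", "%d frames labeled; %d foreground px unreachable from seeds",
         T_, n_orphan)
  movie(out, cal, kind = "labels")
}

#' Curate a labeled movie by merging and excluding labels
#'
#' Merge groups are unified to the smallest id in each group, excluded
#' labels become background, and the remaining labels are renumbered
#' consecutively. Labels touching the image border are reported via the
#' log (exclusion of border-cut cells is the user's decision).
#'
#' @param labeled_movie a label [movie()].
#' @param seeds the matching [seed_labels()] result.
#' @param spec a list with elements `merge` (list of integer vectors) and
#'   `exclude` (integer vector); e.g. `list(merge = list(c(2, 3)), exclude = 7)`.
#' @return A list with the curated `movie` and updated `seeds`.
#' @export
curate_labels <- function(labeled_movie, seeds, spec = list()) {
  stopifnot(inherits(labeled_movie, "morphodyn_movie"))
  merge_groups <- spec$merge %||% list()
  exclude <- as.integer(spec$exclude %||% integer(0))
  ids <- sort(unique(as.integer(seeds$labels[seeds$labels > 0])))
  named <- c(unlist(merge_groups), exclude)
  if (length(named) && !all(named %in% ids))
    stop("curation references unknown label id(s): ",
         paste(setdiff(named, ids), collapse = ", "))
  if (anyDuplicated(unlist(merge_groups)))
    stop("a label id appears in more than one merge group")
  mapping <- seq_len(max(ids, 0L))
  for (g in merge_groups) mapping[g] <- min(g)
  mapping[exclude] <- 0L
  keep <- sort(unique(mapping[mapping > 0 & seq_along(mapping) %in% ids]))
  final <- integer(length(mapping))
  final[keep] <- seq_along(keep)
  comp <- integer(length(mapping)) # old id -> final id (0 = excluded)
  nz <- mapping > 0
  comp[nz] <- final[mapping[nz]]
  remap <- function(x) {
    pos <- x > 0
    x[pos] <- comp[x[pos]]
    x
  }
  arr <- unclass(labeled_movie)
  attrs <- attributes(labeled_movie)
  arr <- remap(arr)
  attributes(arr) <- attrs
  new_seed_lab <- remap(seeds$labels)
  cal <- seeds$calibration
  new_seeds <- structure(list(labels = new_seed_lab,
                              areas_um2 = tabulate(new_seed_lab,
                                                   nbins = length(keep)) *
                                px_area_um2(cal),
                              calibration = cal),
                         class = "morphodyn_seeds")
  # Border report.
  border <- unique(c(arr[1, , ], arr[dim(arr)[1], , ],
                     arr[, 1, ], arr[, dim(arr)[2], ]))
  border <- sort(border[border > 0])
  if (length(border))
    md_log("curate", "label(s) touching the border: %s",
           paste(border, collapse = ", "))
  md_log("curate", "%d label(s) after curation (%d merged away, %d excluded)",
         length(keep), length(unlist(merge_groups)) - length(merge_groups),
         length(exclude))
  list(movie = arr, seeds = new_seeds, border_labels = border)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a labeled movie into per-cell binary movies
#'
#' @param labeled_movie a label [movie()].
#' @return A list of [cell_movie()] objects ordered by label id. A label
#'   absent from some frame yields an empty mask there (flagged via the
#'   `empty_frames` attribute).
#' @export
extract_cell_movies <- function(labeled_movie) {
  stopifnot(inherits(labeled_movie, "morphodyn_movie"))
  cal <- movie_cal(labeled_movie)
  ids <- sort(unique(as.integer(labeled_movie[labeled_movie > 0])))
  lapply(ids, function(id) {
    frames <- lapply(seq_len(n_frames(labeled_movie)), function(t) {
      (get_frame(labeled_movie, t) == id) * 1L
    })
    cm <- cell_movie(frames, cal, cell_id = id)
    empties <- which(vapply(frames, function(f) !any(f > 0), logical(1)))
    if (length(empties)) {
      attr(cm, "empty_frames") <- empties
      md_log("extract", "cell %d absent in %d frame(s)", id, length(empties))
    }
    cm
  })
}
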