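# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (loops, enumeration) and kept separate from the
# package's own algorithms.

mk_square <- function(side_px, canvas = side_px + 20) {
  m <- matrix(FALSE, canvas, canvas)
  o <- floor((canvas - side_px) / 2)
  m[(o + 1):(o + side_px), (o + 1):(o + side_px)] <- TRUE
  m
}

mk_disk <- function(r_px, canvas = 2 * r_px + 21, cy = (canvas + 1) / 2,
                    cx = cy) {
  g <- expand.grid(y = seq_len(canvas), x = seq_len(canvas))
  matrix((g$y - cy)^2 + (g$x - cx)^2 <= r_px^2, canvas, canvas)
}

# 4-armed cross: arms of length `arm` and width `w` (pixels) along the axes
# from the centre of the canvas.
mk_cross <- function(arm_px, w_px, canvas = 2 * arm_px + 2 * w_px + 21) {
  c0 <- ceiling(canvas / 2)
  h <- floor(w_px / 2)
  m <- matrix(FALSE, canvas, canvas)
  m[(c0 - h):(c0 - h + w_px - 1),
    (c0 - arm_px - h):(c0 + arm_px + h)] <- TRUE
  m[(c0 - arm_px - h):(c0 + arm_px + h),
    (c0 - h):(c0 - h + w_px - 1)] <- TRUE
  m
}

# --- matching oracles --------------------------------------------------------

# Minimum total weight over all perfect matchings, by recursion.
enum_min_matching <- function(D) {
  n <- nrow(D)
  best <- Inf
  rec <- function(rem, acc) {
    if (!length(rem)) {
      if (acc < best) best <<- acc
      return(invisible(NULL))
    }
    i <- rem[1]
    for (j in rem[-1]) rec(setdiff(rem, c(i, j)), acc + D[i, j])
  }
  rec(seq_len(n), 0)
  best
}

# All perfect matchings of 1..n as lists of 2-column pair matrices.
enum_all_matchings <- function(n) {
  out <- list()
  rec <- function(rem, acc) {
    if (!length(rem)) {
      out[[length(out) + 1]] <<- acc
      return(invisible(NULL))
    }
    i <- rem[1]
    for (j in rem[-1])
      rec(setdiff(rem, c(i, j)), rbind(acc, c(i, j)))
  }
  rec(seq_len(n), NULL)
  out
}

# Cross-match PMF by enumeration: first m indices are group A, all perfect
# matchings equally likely.
enum_crossmatch_pmf <- function(m, n) {
  ms <- enum_all_matchings(m + n)
  a1s <- vapply(ms, function(pairs)
    sum(xor(pairs[, 1] <= m, pairs[, 2] <= m)), numeric(1))
  tab <- table(a1s) / length(ms)
  data.frame(a1 = as.integer(names(tab)), prob = as.numeric(tab))
}

# --- raster oracles ----------------------------------------------------------

naive_edt <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (!nrow(pts)) return(out)
  for (y in seq_len(nrow(mask)))
    for (x in seq_len(ncol(mask)))
      out[y, x] <- sqrt(min((pts[, 1] - y)^2 + (pts[, 2] - x)^2))
  out
}

naive_morph <- function(mask, offsets, dilate) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    vals <- logical(nrow(offsets))
    for (k in seq_len(nrow(offsets))) {
      qy <- y + (if (dilate) -1 else 1) * offsets[k, 1]
      qx <- x + (if (dilate) -1 else 1) * offsets[k, 2]
      vals[k] <- qy >= 1 && qy <= ny && qx >= 1 && qx <= nx && mask[qy, qx]
    }
    out[y, x] <- if (dilate) any(vals) else all(vals)
  }
  out
}

naive_label <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  cur <- 0L
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (!mask[y, x] || lab[y, x] > 0) next
    cur <- cur + 1L
    queue <- matrix(c(y, x), 1)
    lab[y, x] <- cur
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        qy <- p[1] + nb[k, 1]; qx <- p[2] + nb[k, 2]
        if (qy >= 1 && qy <= ny && qx >= 1 && qx <= nx &&
            mask[qy, qx] && lab[qy, qx] == 0L) {
          lab[qy, qx] <- cur
          queue <- rbind(queue, c(qy, qx))
        }
      }
    }
  }
  lab
}

# Independent re-implementation of the Li fixed-point iteration (different
# initialisation and loop structure from the package's).
oracle_li <- function(v, iters = 500) {
  v <- as.numeric(v)
  t_cur <- stats::median(v)
  for (i in seq_len(iters)) {
    m0 <- mean(v[v < t_cur]); m1 <- mean(v[v >= t_cur])
    t_new <- (m1 - m0) / (log(m1) - log(m0))
    if (abs(t_new - t_cur) < 1e-10) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

# Match recovered cell movies to ground-truth movies by first-frame overlap.
match_cells_to_truth <- function(rec, truth) {
  ov <- vapply(rec, function(rc)
    vapply(truth, function(gt) sum(rc[, , 1] > 0 & gt[, , 1] > 0),
           numeric(1)), numeric(length(truth)))
  apply(matrix(ov, nrow = length(truth)), 2, which.max)
}

# A small, fast tissue world for unit tests (2 cells, 6 frames).
small_tissue <- function(seed = 1L, noise_sd = 0.05, blur_sigma_px = 1) {
  cells <- list(
    synthetic_cell_params(pixel_size_um = 0.3, core_center_um = c(22, 22),
                          duration_s = 70, protrusion_l0_um = 6,
                          protrusion_amplitude_um = 6, seed = seed + 1),
    synthetic_cell_params(pixel_size_um = 0.3, core_center_um = c(58, 58),
                          duration_s = 70, protrusion_l0_um = 6,
                          protrusion_amplitude_um = 6, seed = seed + 2))
  simulate_tissue_movie(cells, frame_size_um = 80, p_fg = 0.9, p_bg = 0.1,
                        blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
                        seed = seed)
}
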