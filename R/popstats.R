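# Population-level statistics: permutation Welch test, exact Rosenbaum
# cross-match test, PCA morphospace.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

welch_stat <- function(m1, v1, n1, m2, v2, n2) {
  den <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / den
  t[den == 0] <- ifelse(m1[den == 0] == m2[den == 0], 0,
                        sign(m1[den == 0] - m2[den == 0]) * Inf)
  t
}

#' Two-sided permutation Welch's t-test
#'
#' The statistic is Welch's unequal-variance t; its null distribution is
#' built by randomly permuting the group labels. The two-sided p-value is
#' `(1 + #{|t*| >= |t_obs|}) / (n_permutations + 1)`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param n_permutations number of label permutations.
#' @param seed optional integer; the test is deterministic given a seed
#'   (the caller's RNG state is restored afterwards).
#' @return List with `p_value`, `t_obs`, `n_permutations`, and significance
#'   `stars` (`*` p<=0.05, `**` p<=0.01, `***` p<=0.001).
#' @export
permutation_welch_test <- function(x, y, n_permutations = 10000, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 observations")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  z <- c(x, y); z2 <- z^2
  tot <- sum(z); tot2 <- sum(z2)
  t_obs <- welch_stat(mean(x), stats::var(x), n1, mean(y), stats::var(y), n2)
  B <- as.integer(n_permutations)
  exceed <- with_seed(seed, {
    idx <- vapply(seq_len(B), function(b) sample.int(N, n1), integer(n1))
    idx <- matrix(idx, nrow = n1)
    s1 <- colSums(matrix(z[idx], nrow = n1))
    ss1 <- colSums(matrix(z2[idx], nrow = n1))
    m1 <- s1 / n1; m2 <- (tot - s1) / n2
    v1 <- pmax(0, (ss1 - n1 * m1^2) / (n1 - 1))
    v2 <- pmax(0, (tot2 - ss1 - n2 * m2^2) / (n2 - 1))
    tstar <- welch_stat(m1, v1, n1, m2, v2, n2)
    sum(abs(tstar) >= abs(t_obs) - 1e-12)
  })
  p <- (1 + exceed) / (B + 1)
  list(p_value = p, t_obs = t_obs, n_permutations = B, stars = p_stars(p))
}

#' Significance star codes
#' @param p p-value(s).
#' @return `"***"` for p <= 0.001, `"**"` for p <= 0.01, `"*"` for
#'   p <= 0.05, `""` otherwise.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (pi <= 0.001) "***" else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*" else ""
  }, character(1))
}

#' Standardized Euclidean distances between pooled observations
#'
#' All pairwise distances among the pooled rows of `A` and `B`:
#' `d(x, y) = sqrt(sum_j (x_j - y_j)^2 / s_j^2)` with `s_j` the pooled
#' sample SD of column j. Zero-variance columns are dropped with a
#' warning.
#'
#' @param A,B numeric matrices with identical columns.
#' @return The `(m + n) x (m + n)` distance matrix, with attribute
#'   `dropped_columns`.
#' @export
standardized_distances <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must share their columns")
  X <- rbind(A, B)
  if (anyNA(X)) stop("undefined entries in feature matrices")
  s <- apply(X, 2, stats::sd)
  dropped <- which(s == 0)
  if (length(dropped) == ncol(X))
    stop("all columns have zero pooled variance")
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance column(s) before standardized distance",
                    length(dropped)))
    X <- X[, -dropped, drop = FALSE]
    s <- s[-dropped]
  }
  X <- sweep(X, 2, s, "/")
  out <- as.matrix(stats::dist(X))
  attr(out, "dropped_columns") <- dropped
  out
}

#' Exact null distribution of the cross-match count
#'
#' Under the permutation null (all group-label assignments to the matched
#' pairs equally likely), the number of between-group pairs `A1` has
#' probability mass
#' `P(A1 = a1) = 2^a1 (N/2)! / (choose(N, m) a0! a1! a2!)` with
#' `a0 = (m - a1)/2`, `a2 = (n - a1)/2`, over all parity-feasible `a1`.
#'
#' @param m,n group sizes; `m + n` must be even.
#' @return `data.frame` with columns `a1` and `prob` (summing to 1).
#' @export
crossmatch_null_pmf <- function(m, n) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 1 || n < 1) stop("group sizes must be >= 1")
  N <- m + n
  if (N %% 2 != 0) stop("m + n must be even (resolve parity before calling)")
  a1 <- seq(m %% 2, min(m, n), by = 2)
  a0 <- (m - a1) / 2
  a2 <- (n - a1) / 2
  lp <- a1 * log(2) + lfactorial(N / 2) -
    (lchoose(N, m) + lfactorial(a0) + lfactorial(a1) + lfactorial(a2))
  data.frame(a1 = a1, prob = exp(lp))
}

#' Exact minimum-weight perfect matching
#'
#' Exact optimum (Edmonds blossom algorithm on the full distance matrix);
#' used by [crossmatch_test()] for the optimal non-bipartite matching.
#'
#' @param D symmetric distance matrix with an even number of rows.
#' @return List with `mate` (index of each point's partner), `pairs`
#'   (2-column matrix, each row one pair) and `total` distance.
#' @export
min_weight_perfect_matching <- function(D) {
  D <- as.matrix(D)
  mate <- cpp_min_weight_perfect_matching(D)
  i <- which(seq_along(mate) < mate)
  pairs <- cbind(i, mate[i])
  dimnames(pairs) <- NULL
  list(mate = mate, pairs = pairs,
       total = sum(D[pairs]))
}

#' Rosenbaum cross-match test for two multivariate samples
#'
#' The pooled observations are paired by an exact minimum-total-distance
#' perfect matching (standardized Euclidean distances); the test statistic
#' `a1` is the number of pairs joining the two groups. Few cross-matches
#' indicate separated distributions, so the reported p-value is the exact
#' lower tail `P(A1 <= a1)` under the permutation null. An odd pooled
#' size is handled by matching with a ghost point at distance zero from
#' every real point and discarding the ghost's pair.
#'
#' @param A,B numeric matrices (rows = observations) with identical
#'   columns; `nrow(A) + nrow(B) >= 4`.
#' @return An object of class `morphodyn_crossmatch`: list with group
#'   sizes (`m`, `n` as given; `m_used`, `n_used` after parity
#'   resolution), `pairs`, `a0`, `a1`, `a2`, `null_pmf`, the exact
#'   `p_value`, a smooth normal-approximation `p_value_approx`, and
#'   `total_distance`.
#' @export
crossmatch_test <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  m <- nrow(A); n <- nrow(B)
  if (m + n < 4) stop("cross-match test requires at least 4 observations")
  D <- standardized_distances(A, B)
  N <- m + n
  ghost <- N %% 2 == 1
  if (ghost) {
    D <- rbind(cbind(D, 0), 0)
  }
  mm <- min_weight_perfect_matching(D)
  pairs <- mm$pairs
  m_used <- m; n_used <- n
  if (ghost) {
    gi <- N + 1
    gpair <- which(pairs[, 1] == gi | pairs[, 2] == gi)
    partner <- setdiff(pairs[gpair, ], gi)
    pairs <- pairs[-gpair, , drop = FALSE]
    if (partner <= m) m_used <- m - 1 else n_used <- n - 1
  }
  in_A <- function(i) i <= m
  cross <- xor(in_A(pairs[, 1]), in_A(pairs[, 2]))
  a1 <- sum(cross)
  a0 <- sum(in_A(pairs[, 1]) & in_A(pairs[, 2]))
  a2 <- sum(!in_A(pairs[, 1]) & !in_A(pairs[, 2]))
  pmf <- crossmatch_null_pmf(m_used, n_used)
  p <- sum(pmf$prob[pmf$a1 <= a1])
  # Normal approximation (closed-form null moments); the exact p is the
  # primary result, but for even group sizes the exact test's attainable
  # sizes are coarse (A1 moves on a lattice of step 2), so the smooth
  # approximation is reported alongside.
  NN <- m_used + n_used
  e_a1 <- m_used * n_used / (NN - 1)
  v_a1 <- 2 * m_used * (m_used - 1) * n_used * (n_used - 1) /
    ((NN - 3) * (NN - 1)^2)
  p_approx <- stats::pnorm((a1 - e_a1) / sqrt(v_a1))
  structure(list(m = m, n = n, m_used = m_used, n_used = n_used,
                 pairs = pairs, a0 = a0, a1 = a1, a2 = a2,
                 null_pmf = pmf, p_value = min(1, p),
                 p_value_approx = p_approx,
                 total_distance = sum(D[pairs])),
            class = "morphodyn_crossmatch")
}

#' @export
print.morphodyn_crossmatch <- function(x, ...) {
  cat(sprintf("Rosenbaum cross-match test: m = %d, n = %d\n", x$m, x$n))
  cat(sprintf("  pairs: %d within-A, %d cross, %d within-B\n",
              x$a0, x$a1, x$a2))
  cat(sprintf("  P(A1 <= %d) = %.4g %s\n", x$a1, x$p_value,
              p_stars(x$p_value)))
  invisible(x)
}

#' PCA morphospace of a quantifier population
#'
#' Columns are z-scored (quantifiers have mixed units), then decomposed by
#' PCA. The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making scores reproducible across row orderings.
#'
#' @param mat population matrix (cells x quantifiers), or a table from
#'   [build_population()].
#' @param k number of components to keep.
#' @return An object of class `morphodyn_morphospace`: list with
#'   `loadings` (quantifiers x k, orthonormal), `explained_variance_ratio`
#'   (all components), `scores` (cells x k), `center`, `scale`, and the
#'   retained `columns`.
#' @export
pca_morphospace <- function(mat, k = 2) {
  if (is.data.frame(mat)) mat <- population_matrix(mat)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("PCA needs at least 2 rows")
  if (nrow(mat) < k + 1) stop("PCA needs at least k + 1 rows")
  ctr <- colMeans(mat)
  scl <- apply(mat, 2, stats::sd)
  keep <- which(scl > 0)
  if (!length(keep)) stop("all columns constant")
  if (length(keep) < ncol(mat))
    warning(sprintf("dropping %d constant column(s) before PCA",
                    ncol(mat) - length(keep)))
  Z <- sweep(sweep(mat[, keep, drop = FALSE], 2, ctr[keep], "-"),
             2, scl[keep], "/")
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pr$rotation))
  L <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(loadings = L, explained_variance_ratio = evr,
                 scores = Z %*% L, center = ctr[keep], scale = scl[keep],
                 columns = colnames(mat)[keep] %||% keep),
            class = "morphodyn_morphospace")
}

#' Export morphospace loadings as a table
#'
#' One row per quantifier, one column per component, plus a final row with
#' each component's explained-variance ratio.
#'
#' @param ms a [pca_morphospace()] result.
#' @return A `data.frame`.
#' @export
loadings_table <- function(ms) {
  stopifnot(inherits(ms, "morphodyn_morphospace"))
  k <- ncol(ms$loadings)
  df <- data.frame(quantifier = c(ms$columns, "explained_variance_ratio"))
  for (j in seq_len(k))
    df[[paste0("PC", j)]] <- c(ms$loadings[, j],
                               ms$explained_variance_ratio[j])
  df
}

#' Kernel density of 2D morphospace scores
#'
#' Gaussian product-kernel density per condition on one shared grid. The
#' bandwidth defaults to Silverman's rule on the pooled scores so that the
#' conditions are directly comparable.
#'
#' @param scores n x 2 matrix of scores.
#' @param condition condition label per row (single group when omitted).
#' @param grid_size number of grid points per axis.
#' @param bandwidth optional length-2 numeric bandwidth.
#' @return List with grid vectors `x`, `y`, the `bandwidth`, and
#'   `densities`: one `grid_size x grid_size` matrix per condition, each
#'   integrating to ~1 over the grid.
#' @export
morphospace_density <- function(scores, condition = NULL, grid_size = 64,
                                bandwidth = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  if (is.null(condition)) condition <- rep("all", nrow(scores))
  condition <- as.character(condition)
  if (any(table(condition) < 2)) stop("need at least 2 points per condition")
  if (is.null(bandwidth))
    bandwidth <- c(stats::bw.nrd0(scores[, 1]), stats::bw.nrd0(scores[, 2]))
  gx <- seq(min(scores[, 1]) - 4 * bandwidth[1],
            max(scores[, 1]) + 4 * bandwidth[1], length.out = grid_size)
  gy <- seq(min(scores[, 2]) - 4 * bandwidth[2],
            max(scores[, 2]) + 4 * bandwidth[2], length.out = grid_size)
  dens <- lapply(split(seq_len(nrow(scores)), condition), function(ix) {
    kx <- outer(gx, scores[ix, 1], function(g, p)
      stats::dnorm(g, p, bandwidth[1]))
    ky <- outer(scores[ix, 2], gy, function(p, g)
      stats::dnorm(g, p, bandwidth[2]))
    (kx %*% ky) / length(ix)
  })
  list(x = gx, y = gy, bandwidth = bandwidth, densities = dens)
}
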