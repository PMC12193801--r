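# Population statistics: permutation Welch, standardized distances,
# cross-match test, PCA morphospace, density.

test_that("permutation Welch test: identity, separation, determinism", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- permutation_welch_test(x, x, 999, seed = 1)
  expect_equal(r$t_obs, 0)
  expect_equal(r$p_value, 1)

  set.seed(7)
  a <- rnorm(30); b <- rnorm(30, 5)
  r2 <- permutation_welch_test(a, b, 10000, seed = 7)
  expect_equal(r2$p_value, 1 / 10001)
  expect_identical(r2$stars, "***")
  # no permuted |t| can exceed the observed one at this separation
  r3 <- permutation_welch_test(a, b, 10000, seed = 99)
  expect_equal(r3$p_value, 1 / 10001)

  expect_identical(permutation_welch_test(a, b, 500, seed = 3)$p_value,
                   permutation_welch_test(a, b, 500, seed = 3)$p_value)
  expect_error(permutation_welch_test(1, c(1, 2)), "at least 2")
  # degenerate: zero variance in both groups, equal means
  expect_equal(permutation_welch_test(rep(2, 5), rep(2, 4), 99,
                                      seed = 1)$p_value, 1)
})

test_that("standardized distances match the naive definition", {
  # 1-D: two points v apart at pooled SD s -> |v| / s
  A <- matrix(c(0), 1); B <- matrix(c(3), 1)
  D <- suppressWarnings(standardized_distances(rbind(A, 1), rbind(B, 2)))
  X <- c(0, 1, 3, 2)
  expect_equal(D[1, 3], 3 / stats::sd(X))
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)

  set.seed(8)
  A <- matrix(rnorm(50), 10, 5); B <- matrix(rnorm(50), 10, 5)
  D2 <- standardized_distances(A, B)
  X <- rbind(A, B)
  s <- apply(X, 2, stats::sd)
  for (i in c(1, 7, 15)) for (j in c(2, 11, 20))
    expect_equal(D2[i, j], sqrt(sum((X[i, ] - X[j, ])^2 / s^2)),
                 tolerance = 1e-10)
  # zero-variance columns are dropped with a warning
  A3 <- cbind(A, 1); B3 <- cbind(B, 1)
  expect_warning(D3 <- standardized_distances(A3, B3), "zero-variance")
  expect_equal(D3, D2, ignore_attr = TRUE)
  expect_error(standardized_distances(matrix(1, 3, 1), matrix(1, 3, 1)),
               "zero pooled variance")
})

test_that("cross-match null PMF matches hand enumeration", {
  p22 <- crossmatch_null_pmf(2, 2)
  expect_equal(p22$prob[p22$a1 == 0], 1 / 3, tolerance = 1e-12)
  expect_equal(p22$prob[p22$a1 == 2], 2 / 3, tolerance = 1e-12)
  p33 <- crossmatch_null_pmf(3, 3)
  expect_equal(p33$prob[p33$a1 == 1], 3 / 5, tolerance = 1e-12)
  expect_equal(p33$prob[p33$a1 == 3], 2 / 5, tolerance = 1e-12)
  for (mn in list(c(1, 3), c(2, 4), c(5, 5), c(20, 20), c(13, 7)))
    expect_equal(sum(crossmatch_null_pmf(mn[1], mn[2])$prob), 1,
                 tolerance = 1e-12)
  expect_error(crossmatch_null_pmf(2, 3), "even")
  # closed-form moments agree with the PMF
  for (mn in list(c(4, 4), c(6, 10), c(20, 20))) {
    pmf <- crossmatch_null_pmf(mn[1], mn[2])
    N <- sum(mn)
    expect_equal(sum(pmf$a1 * pmf$prob), prod(mn) / (N - 1),
                 tolerance = 1e-10)
    v <- 2 * mn[1] * (mn[1] - 1) * mn[2] * (mn[2] - 1) /
      ((N - 3) * (N - 1)^2)
    expect_equal(sum(pmf$a1^2 * pmf$prob) - (prod(mn) / (N - 1))^2, v,
                 tolerance = 1e-10)
  }
})

test_that("cross-match test: separation, interleaving, parity handling", {
  sep <- simulate_feature_population(10, 10, dims = 5, shift = 40, seed = 2)
  r <- crossmatch_test(sep$A, sep$B)
  expect_equal(r$a1, 0)
  expect_equal(r$a0 + r$a1 + r$a2, 10)
  expect_equal(2 * r$a0 + r$a1, 10)
  p0 <- factorial(10) / (factorial(5)^2) / choose(20, 10)
  expect_equal(r$p_value, p0, tolerance = 1e-12)
  expect_equal(r$p_value, 0.00136, tolerance = 0.005)

  # perfectly interleaved 1-D points: neighbours pair up, all cross-matched
  v <- seq_len(20)
  A <- matrix(v[seq(1, 20, 2)]); B <- matrix(v[seq(2, 20, 2)])
  ri <- crossmatch_test(A, B)
  expect_equal(ri$a1, 10)
  expect_equal(ri$p_value, 1)

  # odd pooled size: ghost point discarded, reduced sizes used in the null
  ro <- crossmatch_test(matrix(rnorm(5 * 3), 5), matrix(rnorm(4 * 3), 4))
  expect_equal(ro$m_used + ro$n_used, 8)
  expect_equal(ro$a0 + ro$a1 + ro$a2, 4)
  expect_gt(ro$p_value, 0); expect_lte(ro$p_value, 1)
  expect_error(crossmatch_test(matrix(1, 1, 2), matrix(1, 2, 2)),
               "at least 4")
})

test_that("matching optimality and PMF agree with enumeration (small N)", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(c(6, 8), 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    expect_equal(min_weight_perfect_matching(D)$total, enum_min_matching(D),
                 tolerance = 1e-9)
  }
  for (mn in list(c(2, 2), c(3, 3), c(2, 4), c(1, 5))) {
    want <- enum_crossmatch_pmf(mn[1], mn[2])
    got <- crossmatch_null_pmf(mn[1], mn[2])
    got <- got[got$prob > 1e-14, ]
    expect_equal(got$a1, want$a1)
    expect_equal(got$prob, want$prob, tolerance = 1e-10)
  }
})

test_that("PCA morphospace: rank-1, orthonormality, reconstruction, stability", {
  set.seed(13)
  n <- 20
  # rank-1 variation
  base <- matrix(rnorm(31), n, 31, byrow = TRUE)
  rank1 <- base + outer(rnorm(n), c(1, rep(0, 30)))
  suppressWarnings(ms1 <- pca_morphospace(rank1, k = 2))
  expect_equal(ms1$explained_variance_ratio[1], 1, tolerance = 1e-9)

  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- paste0("q", 1:8)
  ms <- pca_morphospace(X, k = 8)
  expect_equal(t(ms$loadings) %*% ms$loadings, diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  Z <- scale(X)
  expect_equal(ms$scores %*% t(ms$loadings), unclass(Z), tolerance = 1e-8,
               ignore_attr = TRUE)
  # row order invariance (sign convention fixes the components)
  perm <- sample(n)
  ms2 <- pca_morphospace(X[perm, ], k = 3)
  expect_equal(ms2$scores, pca_morphospace(X, k = 3)$scores[perm, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_morphospace(X[1, , drop = FALSE]), "at least 2")
  lt <- loadings_table(ms)
  expect_equal(nrow(lt), 9) # 8 quantifiers + explained variance row
})

test_that("morphospace density integrates to 1 and separates shifted modes", {
  set.seed(14)
  s1 <- cbind(rnorm(40, 0, 0.5), rnorm(40, 0, 0.5))
  s2 <- cbind(rnorm(40, 6, 0.5), rnorm(40, 6, 0.5))
  dn <- morphospace_density(rbind(s1, s2), rep(c("a", "b"), each = 40),
                            grid_size = 80)
  dx <- diff(dn$x[1:2]); dy <- diff(dn$y[1:2])
  for (cond in c("a", "b"))
    expect_equal(sum(dn$densities[[cond]]) * dx * dy, 1, tolerance = 0.01)
  pk <- function(z) {
    ij <- which(z == max(z), arr.ind = TRUE)[1, ]
    c(dn$x[ij[1]], dn$y[ij[2]])
  }
  expect_equal(pk(dn$densities$a), c(0, 0), tolerance = 0.5)
  expect_equal(pk(dn$densities$b), c(6, 6), tolerance = 0.5)
  expect_error(morphospace_density(s1[1, , drop = FALSE]), "at least 2")
})

test_that("cross-match power rises monotonically with the population shift", {
  # Scaled to 80 replicates per shift (nominal design: 200) to stay inside the
  # suite's time budget; the ordering is far from the noise floor.
  set.seed(16)
  rates <- vapply(c(0, 1, 2, 3), function(shift) {
    res <- vapply(seq_len(80), function(i) {
      p <- simulate_feature_population(20, 20, 31, shift,
                                       seed = sample.int(2^30, 1))
      r <- crossmatch_test(p$A, p$B)
      c(r$p_value <= 0.05, r$p_value_approx <= 0.05, r$a1)
    }, numeric(3))
    rowMeans(res)
  }, numeric(3))
  expect_true(all(diff(rates[1, ]) >= 0))      # exact-test power
  expect_true(all(diff(rates[2, ]) > 0))       # smooth-approximation power
  expect_true(all(diff(rates[3, ]) < 0))       # mean a1 falls with the shift
  expect_gte(rates[2, 4], 0.8)                 # strong power at shift 3
})

test_that("permutation Welch rejects at roughly nominal rate under the null", {
  set.seed(15)
  pv <- replicate(300, permutation_welch_test(rnorm(15), rnorm(15), 199)$p_value)
  rej <- mean(pv <= 0.05)
  expect_gt(rej, 0.015); expect_lt(rej, 0.1)
})
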