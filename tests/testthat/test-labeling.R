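# Segmentation and labeling stages.

test_that("Li threshold: separable, mixture, and degenerate cases", {
  # two-valued frame: threshold falls strictly between the levels
  v <- c(rep(0.1, 900), rep(0.9, 100))
  t0 <- li_threshold(v)
  expect_gt(t0, 0.1)
  expect_lte(t0, 0.9)
  # and the fixed point of the Li iteration matches its closed form here
  expect_equal(t0, 0.8 / (log(0.9) - log(0.1)), tolerance = 1e-6)

  # Gaussian mixture: threshold separates the modes and agrees with an
  # independent fixed-point iteration of the Li criterion
  set.seed(1)
  v <- c(rnorm(4000, 0.2, 0.05), rnorm(1000, 0.8, 0.05))
  t1 <- li_threshold(v)
  expect_gt(t1, 0.3); expect_lt(t1, 0.7)
  expect_equal(t1, oracle_li(v), tolerance = 1e-5)

  expect_true(is.na(li_threshold(rep(0.5, 100))))
})

test_that("binarize_movie thresholds per frame and flags constant frames", {
  cal <- calibration(1, 1)
  f1 <- matrix(0.1, 20, 20); f1[5:10, 5:10] <- 0.9
  f2 <- matrix(0.5, 20, 20) # constant
  m <- movie(list(f1, f2), cal, "probability")
  expect_warning(b <- binarize_movie(m), "constant")
  expect_identical(b[, , 1] > 0, f1 == 0.9)
  expect_true(all(b[, , 2] == 0))
})

test_that("clean_binary_frame fills small holes, removes specks, is idempotent", {
  cal <- calibration(1, 1) # 1 um/px so px == um^2
  cfg <- pipeline_config()
  m <- matrix(FALSE, 40, 40)
  m[10:29, 10:29] <- TRUE            # 20x20 um square
  m[15:16, 15:17] <- FALSE           # 6 um^2 hole < 10 -> filled
  m[35:37, 35:37] <- TRUE            # 9 um^2 speck < 10 -> removed
  pat <- outer(-2:2, -2:2, function(a, b) a^2 + b^2 <= 4)
  m[3:7, 28:32] <- m[3:7, 28:32] | pat # 13 um^2 round object >= 10 -> kept
  out <- clean_binary_frame(m, cfg, cal)
  expect_true(all(out[15:16, 15:17]))
  expect_false(any(out[35:37, 35:37]))
  expect_true(any(out[3:7, 28:32]))
  expect_identical(clean_binary_frame(out, cfg, cal), out)
  expect_false(any(clean_binary_frame(matrix(FALSE, 10, 10), cfg, cal)))
})

test_that("opening removes structures thinner than the disk", {
  # 1-px filament, 0.3 um/px, opening radius 0.6 um (2 px disk)
  cal <- calibration(0.3, 1)
  cfg <- pipeline_config(min_object_area_um2 = 0.01) # isolate the opening
  m <- matrix(FALSE, 50, 50)
  m[25, 10:43] <- TRUE # ~10 um long, 1 px wide
  out <- clean_binary_frame(m, cfg, cal)
  # oracle: direct erosion-then-dilation
  se <- morphodyn:::disk_offsets(2)
  oracle <- naive_morph(naive_morph(m, se, FALSE), se, TRUE)
  expect_identical(out, oracle)
  expect_false(any(out))
})

test_that("seed labels: threshold and size-filter bracketing", {
  cal <- calibration(1, 1)
  cfg <- pipeline_config()
  # static movie with two disks of ~80 um^2 -> 2 seeds
  d <- mk_disk(5, 60) | mk_disk(5, 60, cy = 45, cx = 45)
  m <- movie(lapply(1:3, function(i) d * 1L), cal, "binary")
  s <- seed_labels(m, cfg)
  expect_equal(max(s$labels), 2)

  # occupancy 96/100 excluded, 97/100 included (>= 0.97)
  base <- mk_square(12, 40) # 144 um^2, above the 50 um^2 seed filter
  px <- which(base, arr.ind = TRUE)[1, ]
  frames <- lapply(1:100, function(i) base * 1L)
  for (i in 1:4) frames[[i]][px[1], px[2]] <- 0L # pixel present 96/100
  s96 <- seed_labels(movie(frames, cal, "binary"), cfg)
  expect_false(s96$labels[px[1], px[2]] > 0)
  frames[[4]][px[1], px[2]] <- 1L # now 97/100
  s97 <- seed_labels(movie(frames, cal, "binary"), cfg)
  expect_true(s97$labels[px[1], px[2]] > 0)

  # 45 vs 55 um^2 around the 50 um^2 cutoff
  m45 <- matrix(FALSE, 40, 40); m45[5:9, 5:13] <- TRUE      # 45 um^2
  m55 <- matrix(FALSE, 40, 40); m55[25:29, 20:30] <- TRUE   # 55 um^2
  s2 <- seed_labels(movie(list((m45 | m55) * 1L), cal, "binary"), cfg)
  expect_equal(max(s2$labels), 1)
  expect_true(s2$labels[27, 25] > 0)

  # raising the seed size filter never increases the seed count
  set.seed(3)
  blobs <- mk_disk(4, 70) | mk_disk(6, 70, 20, 50) | mk_disk(8, 70, 55, 30)
  mv <- movie(list(blobs * 1L), cal, "binary")
  counts <- vapply(c(10, 50, 120, 250), function(a)
    max(suppressWarnings( # the largest filter empties the seed mask
      seed_labels(mv, pipeline_config(seed_min_area_um2 = a)))$labels),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_warning(seed_labels(movie(list(matrix(0L, 10, 10)), cal, "binary"),
                             cfg), "empty seed mask")
})

test_that("label_cells covers one-object identity and partitions foreground", {
  cal <- calibration(1, 1)
  cfg <- pipeline_config()
  d <- mk_disk(6, 40)
  mv <- movie(lapply(1:3, function(i) d * 1L), cal, "binary")
  seeds <- seed_labels(mv, cfg)
  labs <- label_cells(mv, seeds, cfg)
  expect_identical(labs[, , 2] > 0, d)
  expect_true(all(labs[, , 2][d] == 1))
  # partition: every foreground pixel carries exactly one label
  expect_identical(labs[, , 1] > 0, d)
  expect_error(label_cells(movie(list(matrix(0L, 5, 5)), cal, "binary"),
                           seeds, cfg), "shape mismatch")
})

test_that("dilation pass re-attaches protrusion fragments near the cell", {
  cal <- calibration(1, 1)
  cfg <- pipeline_config() # diamond radius 2.2 um -> 2 px
  body <- mk_disk(8, 60, cy = 30, cx = 20)
  frag <- matrix(FALSE, 60, 60); frag[29:31, 32:35] <- TRUE
  far <- matrix(FALSE, 60, 60); far[5:7, 50:53] <- TRUE
  frame <- (body | frag | far) * 1L
  mv <- movie(lapply(1:2, function(i) frame), cal, "binary")
  seeds <- seed_labels(mv, pipeline_config())
  expect_equal(max(seeds$labels), 1) # only the body survives the 50 um^2 filter
  labs <- label_cells(mv, seeds, cfg)
  # gap body..frag is 3 px <= 2 * dilation radius -> same label as the body
  expect_true(all(labs[, , 1][frag] == 1))
  # the far fragment is unreachable and stays background
  expect_true(all(labs[, , 1][far] == 0))
})

test_that("curation merges, excludes, renumbers and validates", {
  cal <- calibration(1, 1)
  cfg <- pipeline_config()
  blobs <- mk_disk(5, 80, 15, 15) | mk_disk(5, 80, 15, 60) |
    mk_disk(5, 80, 60, 15) | mk_disk(5, 80, 60, 60)
  mv <- movie(list(blobs * 1L, blobs * 1L), cal, "binary")
  seeds <- seed_labels(mv, cfg)
  labs <- label_cells(mv, seeds, cfg)
  expect_equal(max(seeds$labels), 4)
  cur <- curate_labels(labs, seeds, list(merge = list(c(2, 3)), exclude = 4))
  ids <- sort(unique(as.integer(cur$movie[cur$movie > 0])))
  expect_identical(ids, c(1L, 2L)) # 4 -> merged to 3 -> renumbered
  expect_error(curate_labels(labs, seeds, list(exclude = 9)), "unknown label")
  expect_error(curate_labels(labs, seeds,
                             list(merge = list(c(1, 2), c(2, 3)))),
               "more than one merge group")
})

test_that("extract_cell_movies partitions the labeled movie", {
  cal <- calibration(1, 1)
  cfg <- pipeline_config()
  blobs3 <- mk_disk(5, 80, 15, 15) | mk_disk(5, 80, 40, 60) |
    mk_disk(5, 80, 65, 20)
  mv <- movie(list(blobs3 * 1L, blobs3 * 1L), cal, "binary")
  labs <- label_cells(mv, seed_labels(mv, cfg), cfg)
  cms <- extract_cell_movies(labs)
  expect_length(cms, 3)
  un <- Reduce(`|`, lapply(cms, function(cm) cm[, , 1] > 0))
  expect_identical(un, labs[, , 1] > 0)
  # pairwise disjoint
  expect_equal(Reduce(`+`, lapply(cms, function(cm) (cm[, , 1] > 0) * 1)),
               (labs[, , 1] > 0) * 1)
  expect_length(extract_cell_movies(movie(list(matrix(0L, 5, 5)), cal,
                                          "labels")), 0)
})
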