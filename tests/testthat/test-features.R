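# Per-frame and per-movie morphology features.

test_that("shape features are exact on analytic shapes", {
  cal <- calibration(1, 1)
  cfg <- pipeline_config()
  fs <- frame_shape_features(mk_square(100), cal, cfg)
  expect_equal(fs$area_um2, 10000)
  expect_equal(fs$solidity, 1, tolerance = 1e-9)
  expect_equal(fs$convexity, 1, tolerance = 1e-9)
  expect_equal(fs$aspect_ratio, 1, tolerance = 1e-9)
  expect_equal(fs$circularity, pi / 4, tolerance = 0.02)

  fd <- frame_shape_features(mk_disk(50), cal, cfg)
  expect_gte(fd$circularity, 0.98)
  expect_gte(fd$solidity, 0.98)
  expect_lte(fd$angularity, 0.05)

  expect_error(frame_shape_features(matrix(FALSE, 5, 5), cal, cfg), "empty")
})

test_that("cross solidity matches the exact polygon-hull oracle", {
  # arms 20 x 4 um at 0.5 um/px: cross area 336 um^2, hull octagon 1136 um^2
  cal <- calibration(0.5, 1)
  m <- mk_cross(40, 8) # pixels
  fs <- frame_shape_features(m, cal, pipeline_config())
  cross_area <- 2 * 44 * 4 - 4 * 4
  hull_area <- 44^2 - 4 * (20^2 / 2)
  expect_equal(fs$area_um2, cross_area, tolerance = 0.02)
  expect_equal(fs$solidity, cross_area / hull_area, tolerance = 0.01 * 3)
})

test_that("fixed/mobile decomposition follows the occupancy definition", {
  cal <- calibration(1, 1)
  cfg <- pipeline_config()
  core <- mk_disk(6, 40)
  prot <- matrix(FALSE, 40, 40); prot[19:22, 27:34] <- TRUE
  # static movie: fixed mask is the mask, mobile area 0
  mv <- cell_movie(lapply(1:4, function(i) core * 1L), cal)
  fm <- fixed_mobile(mv, cfg)
  expect_identical(fm$fixed_mask, core)
  expect_true(all(fm$mobile_area_um2 == 0))

  # protrusion present 50% of frames: fixed = core, mean mobile = half area
  frames <- lapply(1:10, function(i) ((core | (i %% 2 == 0 & prot)) * 1L))
  fm2 <- fixed_mobile(cell_movie(frames, cal), cfg)
  expect_identical(fm2$fixed_mask, core)
  expect_equal(mean(fm2$mobile_area_um2), sum(prot) / 2)

  # 96/100 vs 97/100 occupancy at the 0.97 threshold
  frames <- lapply(1:100, function(i) core * 1L)
  px <- which(core, arr.ind = TRUE)[1, ] # a pixel actually inside the core
  for (i in 1:4) frames[[i]][px[1], px[2]] <- 0L
  expect_false(fixed_mobile(cell_movie(frames, cal),
                            cfg)$fixed_mask[px[1], px[2]])
  frames[[4]][px[1], px[2]] <- 1L
  expect_true(fixed_mobile(cell_movie(frames, cal),
                           cfg)$fixed_mask[px[1], px[2]])
})

test_that("max protrusion length is the directed Hausdorff distance", {
  cal <- calibration(0.5, 1)
  fixed <- mk_disk(20, 140, cy = 70, cx = 40) # radius 10 um
  expect_equal(max_protrusion_length(fixed, fixed, cal), 0)

  # bar reaching x = 30 um from the centre -> 20 um beyond the outline
  bar <- matrix(FALSE, 140, 140); bar[68:72, 40:100] <- TRUE
  cell <- fixed | bar
  expect_equal(max_protrusion_length(cell, fixed, cal), 20, tolerance = 0.8)

  # unsigned: mask eroded 3 um inside the fixed mask -> 3 um
  se <- morphodyn:::disk_offsets(6)
  inner <- cpp_binary_morph(fixed, se, FALSE)
  expect_equal(max_protrusion_length(inner, fixed, cal), 3, tolerance = 0.8)
  expect_error(max_protrusion_length(cell, matrix(FALSE, 140, 140), cal),
               "empty")
})

test_that("protrusiveness counts Sholl arcs", {
  cal <- calibration(0.5, 1)
  cfg <- pipeline_config()
  disk20 <- mk_disk(40, 120) # radius 20 um
  expect_equal(protrusiveness(disk20, disk20, cal, cfg), 2L)
  # 4-armed cross, arms 20 um: 4 arcs on each of the 8 and 16 um rings
  cross <- mk_cross(40, 8, 121)
  centre <- mk_disk(6, 121)
  expect_equal(protrusiveness(cross, centre, cal, cfg), 8L)
  # radial extent below the first ring -> 0
  small <- mk_disk(10, 40) # 5 um radius
  expect_equal(protrusiveness(small, small, cal, cfg), 0L)
})

test_that("dynamic area change is the lagged symmetric difference", {
  cal <- calibration(0.5, 14)
  cfg <- pipeline_config() # 14 s lag -> 1 frame
  sq <- mk_square(20, 60)
  mv <- cell_movie(list(sq * 1L, sq * 1L, sq * 1L), cal)
  expect_true(all(dynamic_area_change(mv, cfg) == 0))

  # disjoint masks: DAC = A1 + A2
  a <- matrix(FALSE, 60, 60); a[5:14, 5:14] <- TRUE
  b <- matrix(FALSE, 60, 60); b[40:49, 40:49] <- TRUE
  mv2 <- cell_movie(list(a * 1L, b * 1L), cal)
  expect_equal(as.numeric(dynamic_area_change(mv2, cfg)),
               (sum(a) + sum(b)) * 0.25)

  # 10x10 um square translated 2 um along x -> 40 um^2
  s1 <- matrix(FALSE, 60, 60); s1[20:39, 20:39] <- TRUE
  s2 <- matrix(FALSE, 60, 60); s2[20:39, 24:43] <- TRUE
  mv3 <- cell_movie(list(s1 * 1L, s2 * 1L), cal)
  expect_equal(as.numeric(dynamic_area_change(mv3, cfg)), 40)

  expect_error(dynamic_area_change(cell_movie(list(s1 * 1L), cal), cfg),
               "too short")
  # metric properties: symmetry and triangle bound on random masks
  set.seed(5)
  xor_area <- function(x, y) sum(xor(x, y))
  for (i in 1:20) {
    ms <- lapply(1:3, function(j) matrix(runif(100) < 0.5, 10, 10))
    expect_identical(xor_area(ms[[1]], ms[[2]]), xor_area(ms[[2]], ms[[1]]))
    expect_lte(xor_area(ms[[1]], ms[[3]]),
               xor_area(ms[[1]], ms[[2]]) + xor_area(ms[[2]], ms[[3]]))
  }
})

test_that("feature time series: static limit, oscillation, schema", {
  cfg <- pipeline_config()
  static <- simulate_cell_movie(synthetic_cell_params(
    protrusion_amplitude_um = 0, duration_s = 70, seed = 2))
  ts <- feature_timeseries(static$movie, cfg)
  expect_equal(nrow(ts$frames), dim(static$movie)[3])
  for (col in c("area_um2", "perimeter_um", "solidity", "convexity",
                "circularity", "aspect_ratio", "angularity"))
    expect_equal(stats::sd(ts$frames[[col]]), 0)

  osc <- simulate_cell_movie(synthetic_cell_params(
    protrusion_amplitude_um = 4, protrusion_period_s = 120,
    duration_s = 240, seed = 4))
  ts2 <- feature_timeseries(osc$movie, cfg)
  expect_true(isTRUE(ts2$usable))
  # extension wrinkles the outline: convexity anti-correlates with
  # protrusion length over the oscillation
  expect_lt(cor(ts2$frames$convexity, ts2$frames$max_protrusion_um), 0)
})

test_that("bounded features stay in [0,1] and scale consistently", {
  cfg <- pipeline_config()
  bounded <- c("solidity", "convexity", "circularity", "aspect_ratio",
               "angularity")
  # Scaled down from the nominal 1000 random shapes to 6 movies
  # (~25 frames) to stay inside the suite's time budget.
  set.seed(6)
  for (seed in 1:6) {
    sim <- simulate_cell_movie(synthetic_cell_params(
      duration_s = 42, seed = seed,
      protrusion_amplitude_um = runif(1, 0, 4),
      n_protrusions = sample(0:7, 1)))
    ts <- feature_timeseries(sim$movie, cfg)
    for (col in bounded) {
      expect_true(all(ts$frames[[col]] >= 0 & ts$frames[[col]] <= 1))
    }
    expect_true(all(ts$frames$protrusiveness >= 0 &
                    ts$frames$protrusiveness == round(ts$frames$protrusiveness)))
  }

  # doubling resolution at fixed physical geometry
  p1 <- synthetic_cell_params(pixel_size_um = 0.5, duration_s = 14, seed = 9)
  p2 <- synthetic_cell_params(pixel_size_um = 0.25, duration_s = 14, seed = 9)
  f1 <- frame_shape_features(simulate_cell_movie(p1)$movie[, , 1] > 0,
                             calibration(0.5, 14), cfg)
  f2 <- frame_shape_features(simulate_cell_movie(p2)$movie[, , 1] > 0,
                             calibration(0.25, 14), cfg)
  expect_lt(abs(f1$area_um2 / f2$area_um2 - 1), 0.02)
  expect_lt(abs(f1$perimeter_um / f2$perimeter_um - 1), 0.02)
  for (col in bounded) expect_lt(abs(f1[[col]] - f2[[col]]), 0.02)
})
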