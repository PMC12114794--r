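test_that("forest masks exclude non-forest classes under nearest-neighbour resampling", {
  legend <- landcover_legend_codes()
  # all-forest map -> all ones
  lc <- forest_landcover(8, 8)
  fm <- build_forest_mask(lc, legend[["forest"]])
  expect_true(all(fm$mask == 1))
  # identity grid: mask equals the per-pixel code test
  classes <- matrix(1L, 6, 6)
  classes[2, 2] <- 2L; classes[5, 3] <- 3L
  lc2 <- land_cover_map(classes, grid_spec(6, 6, 10, c(0, 60)), legend)
  fm2 <- build_forest_mask(lc2, legend[["forest"]])
  expect_equal(fm2$mask, matrix(as.integer(classes == 1L), 6, 6))
  # 10 m -> 30 m: the 30 m pixel takes the class of the source pixel under
  # its centre (row 2, col 2 of the 6x6 map), here water -> 0
  fm3 <- build_forest_mask(lc2, legend[["forest"]], grid_spec(2, 2, 30, c(0, 60)))
  expect_equal(fm3$mask[1, 1], 0L)
  expect_equal(fm3$mask[1, 2], 1L)
  expect_error(build_forest_mask(lc2, integer(0)), "non-empty")
  expect_error(build_forest_mask(lc2, 99L), "legend")
})

test_that("point sampling reads the containing pixel without interpolation", {
  sc <- constant_scene(4, 4, 0.3)
  ctr <- pixel_centres(sc$grid)
  s <- sample_raster_values(sc, data.frame(x = ctr$x[2], y = ctr$y[3]))
  expect_equal(unname(unlist(s[1, sc$bands])), rep(0.3, 4))
  # two points in the same pixel give identical values
  sc2 <- indexed_scene(2, 2)
  pts <- data.frame(x = c(0.2, 0.8), y = c(1.9, 1.1)) # both in pixel (1,1)
  s2 <- sample_raster_values(sc2, pts)
  expect_equal(s2$NIR[1], s2$NIR[2])
  # hand-checked containing-pixel arithmetic: (1.5, 0.5) -> row 2, col 2
  s3 <- sample_raster_values(sc2, data.frame(x = 1.5, y = 0.5))
  expect_equal(s3$Blue, sc2$values[2, 2, 1])
  expect_error(sample_raster_values(sc2, data.frame(x = 5, y = 1)),
               "outside the raster extent")
  expect_error(sample_raster_values(sc2, data.frame(x = numeric(0), y = numeric(0))),
               "non-empty")
})

test_that("band ranges are the per-band min/max of the samples", {
  sc <- indexed_scene(3, 3)
  ctr <- pixel_centres(sc$grid)
  pts <- expand.grid(x = ctr$x, y = ctr$y)
  s <- sample_raster_values(sc, pts)
  r <- compute_band_ranges(s)
  for (b in sc$bands) {
    expect_equal(r$min[r$band == b], min(s[[b]]))
    expect_equal(r$max[r$band == b], max(s[[b]]))
  }
  # single sample: min == max
  s1 <- sample_raster_values(sc, pts[1, ])
  r1 <- compute_band_ranges(s1)
  expect_equal(r1$min, r1$max)
  # adding a sample never narrows a range
  r2 <- compute_band_ranges(s[1:4, ])
  r3 <- compute_band_ranges(s[1:5, ])
  expect_true(all(r3$min <= r2$min) && all(r3$max >= r2$max))
})

test_that("threshold classification is a conjunction over inclusive band ranges", {
  sc <- indexed_scene(3, 3)
  fm <- forest_mask(matrix(1L, 3, 3), sc$grid)
  # ranges covering pixels 1..4 (values .101-.404 etc. per band)
  ranges <- tibble::tibble(
    band = sc$bands,
    min = vapply(1:4, function(b) (b * 100 + 1) / 1000, numeric(1)),
    max = vapply(1:4, function(b) (b * 100 + 4) / 1000, numeric(1))
  )
  out <- threshold_classify(sc, ranges, fm)
  # exhaustive oracle: check every pixel against every band by hand
  expected <- matrix(0L, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    ok <- TRUE
    for (b in 1:4) {
      v <- sc$values[i, j, b]
      ok <- ok && v >= ranges$min[b] && v <= ranges$max[b]
    }
    expected[i, j] <- as.integer(ok)
  }
  expect_equal(out$mask, expected)
  expect_equal(sum(out$mask), 4)
  # one band out of range excludes the pixel
  ranges2 <- ranges
  ranges2$max[4] <- ranges2$min[4] # NIR collapses to pixel 1 only
  expect_equal(sum(threshold_classify(sc, ranges2, fm)$mask), 1)
  # forest exclusion
  fm0 <- forest_mask(matrix(0L, 3, 3), sc$grid)
  expect_equal(sum(threshold_classify(sc, ranges, fm0)$mask), 0)
  # band mismatch errors
  bad <- tibble::tibble(band = "SWIR", min = 0, max = 1)
  expect_error(threshold_classify(sc, bad, fm), "SWIR")
})

test_that("widening any band range can only add burnt pixels", {
  set.seed(8)
  sc <- reflectance_scene(array(runif(10 * 10 * 4), c(10, 10, 4)),
                          grid_spec(10, 10, 3), c("Blue", "Green", "Red", "NIR"))
  fm <- forest_mask(matrix(1L, 10, 10), sc$grid)
  r1 <- tibble::tibble(band = sc$bands, min = rep(0.3, 4), max = rep(0.6, 4))
  r2 <- tibble::tibble(band = sc$bands, min = rep(0.2, 4), max = rep(0.7, 4))
  m1 <- threshold_classify(sc, r1, fm)$mask
  m2 <- threshold_classify(sc, r2, fm)$mask
  expect_true(all(m2[m1 == 1] == 1))
})

test_that("label transfer matches an explicit block-summing oracle", {
  set.seed(3)
  m <- matrix(as.integer(runif(40 * 40) < 0.35), 40, 40)
  bm <- burn_mask(m, grid_spec(40, 40, 3))
  for (th in c(0.25, 0.5, 1)) {
    out <- transfer_labels(bm, 10, th)
    oracle <- matrix(0L, 4, 4)
    for (bi in 1:4) for (bj in 1:4) {
      blk <- m[(bi - 1) * 10 + 1:10, (bj - 1) * 10 + 1:10]
      oracle[bi, bj] <- as.integer(sum(blk) / 100 >= th)
    }
    expect_equal(out$mask, oracle, info = paste("threshold", th))
  }
  # all-burnt input stays all-burnt at any threshold <= 1
  allb <- burn_mask(matrix(1L, 20, 20), grid_spec(20, 20, 3))
  expect_true(all(transfer_labels(allb, 10, 1)$mask == 1))
})

test_that("threshold labelling recovers ground truth exactly on separable noise-free scenes", {
  cfg <- tiny_easy_config(seed = 19)
  pair <- simulate_scene_pair(cfg)
  pts <- sample_points_from_mask(pair$vhr_truth, 50, seed = 4)
  ranges <- compute_band_ranges(sample_raster_values(pair$vhr, pts))
  lab <- threshold_classify(pair$vhr, ranges, pair$forest_vhr)
  expect_identical(lab$mask, pair$vhr_truth$mask)
})

test_that("scar sampling returns burnt pixel centres", {
  cfg <- tiny_easy_config(seed = 23)
  pair <- simulate_scene_pair(cfg)
  pts <- sample_points_from_mask(pair$vhr_truth, 30, seed = 9)
  loc <- crossburn:::locate_points(pair$vhr_truth$grid, pts$x, pts$y)
  expect_true(all(pair$vhr_truth$mask[cbind(loc$row, loc$col)] == 1))
  # deterministic given the seed
  pts2 <- sample_points_from_mask(pair$vhr_truth, 30, seed = 9)
  expect_identical(pts, pts2)
})
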