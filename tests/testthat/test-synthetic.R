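test_that("land-cover generation is deterministic and hits requested fractions", {
  cfg <- scene_config(height = 500, width = 500, landcover_smoothness = 15,
                      class_fractions = c(forest = 0.70, water = 0.20,
                                          road_urban = 0.04, barren = 0.06),
                      seed = 11)
  lc1 <- generate_land_cover(cfg)
  lc2 <- generate_land_cover(cfg)
  expect_identical(lc1$classes, lc2$classes)
  water_frac <- mean(lc1$classes == lc1$legend[["water"]])
  expect_lt(abs(water_frac - 0.20), 0.05)
})

test_that("all-forest composition yields an all-forest map", {
  cfg <- scene_config(height = 60, width = 60,
                      class_fractions = c(forest = 1, water = 0,
                                          road_urban = 0, barren = 0),
                      landcover_pixel_size = 3, seed = 2)
  lc <- generate_land_cover(cfg)
  expect_true(all(lc$classes == lc$legend[["forest"]]))
})

test_that("burn masks stay inside forest at the requested fraction", {
  cfg <- tiny_config(seed = 5)
  lc <- generate_land_cover(cfg)
  bm <- generate_burn_mask(lc, cfg)
  frac <- mean(bm$mask)
  expect_lt(abs(frac - cfg$burn_fraction_target), 0.01)
  forest_vhr <- crossburn:::resample_nearest(lc$classes, lc$grid, cfg$vhr_grid) ==
    lc$legend[["forest"]]
  expect_equal(sum(bm$mask == 1 & !forest_vhr), 0)
  # determinism
  expect_identical(generate_burn_mask(lc, cfg)$mask, bm$mask)
})

test_that("zero burn target gives an empty mask; infeasible targets error", {
  cfg0 <- tiny_config(burn_fraction_target = 0)
  lc <- generate_land_cover(cfg0)
  expect_equal(sum(generate_burn_mask(lc, cfg0)$mask), 0)
  cfg_bad <- tiny_config(burn_fraction_target = 0.9,
                         class_fractions = c(forest = 0.5, water = 0.5,
                                             road_urban = 0, barren = 0))
  lc2 <- generate_land_cover(cfg_bad)
  expect_error(generate_burn_mask(lc2, cfg_bad), "infeasible")
})

test_that("rendering without noise reproduces class means exactly", {
  cfg <- tiny_easy_config(seed = 9)
  lc <- generate_land_cover(cfg)
  bm <- generate_burn_mask(lc, cfg)
  sc <- render_vhr_scene(lc, bm, cfg)
  classes <- crossburn:::resample_nearest(lc$classes, lc$grid, cfg$vhr_grid)
  forest_px <- which(classes == lc$legend[["forest"]] & bm$mask == 0)[1]
  burnt_px <- which(bm$mask == 1)[1]
  nir <- sc$values[, , match("NIR", sc$bands)]
  expect_equal(nir[forest_px], cfg$spectra$forest$mean[["NIR"]])
  expect_equal(nir[burnt_px], cfg$spectra$burnt$mean[["NIR"]])
})

test_that("rendered per-class sample means match configured means under noise", {
  # a mid-range spectrum keeps the [0, 1] clipping inactive, so the sample
  # mean over 4e4 pixels is an unbiased estimate of the configured mean
  bn <- c("Blue", "Green", "Red", "NIR")
  spectra <- default_spectra()
  spectra$forest <- class_spectrum(stats::setNames(c(0.4, 0.5, 0.55, 0.6), bn),
                                   0.02)
  cfg <- scene_config(height = 200, width = 200,
                      class_fractions = c(forest = 1, water = 0,
                                          road_urban = 0, barren = 0),
                      spectra = spectra,
                      burn_fraction_target = 0, vhr_noise_sd = 0, seed = 21)
  lc <- generate_land_cover(cfg)
  bm <- generate_burn_mask(lc, cfg)
  sc <- render_vhr_scene(lc, bm, cfg)
  for (b in seq_along(cfg$bands)) {
    mu <- cfg$spectra$forest$mean[[cfg$bands[b]]]
    se <- cfg$spectra$forest$sd[[cfg$bands[b]]] / sqrt(200 * 200)
    expect_lt(abs(mean(sc$values[, , b]) - mu), 4 * se)
  }
})

test_that("rendering fails when a present class has no spectrum", {
  cfg <- tiny_easy_config()
  cfg$spectra$water <- NULL
  lc <- generate_land_cover(cfg)
  bm <- generate_burn_mask(lc, cfg)
  expect_error(render_vhr_scene(lc, bm, cfg), "no spectrum")
})

test_that("block aggregation is an exact arithmetic mean", {
  # constant image stays constant
  sc <- constant_scene(20, 20, 0.3)
  med <- degrade_to_medium(sc, 10)
  expect_true(all(abs(med$values - 0.3) < 1e-12))
  expect_equal(med$grid$pixel_size, 30)
  # 10x10 block: 40 px at 0.05, 60 at 0.30 -> mean 0.20
  vals <- array(0.30, c(10, 10, 1))
  vals[1:4, , 1] <- 0.05
  sc2 <- reflectance_scene(vals, grid_spec(10, 10, 3), "NIR")
  expect_equal(degrade_to_medium(sc2, 10)$values[1, 1, 1], 0.20)
  expect_error(degrade_to_medium(sc, 0), "factor")
})

test_that("aggregation conserves the per-band global mean without noise", {
  cfg <- tiny_config(seed = 31)
  pair_scene <- render_vhr_scene(generate_land_cover(cfg),
                                 generate_burn_mask(generate_land_cover(cfg), cfg),
                                 cfg)
  med <- degrade_to_medium(pair_scene, cfg$factor)
  for (b in seq_along(cfg$bands)) {
    expect_lt(abs(mean(med$values[, , b]) - mean(pair_scene$values[, , b])), 1e-9)
  }
})

test_that("coverage-threshold transfer follows the >= convention", {
  m <- matrix(0L, 10, 10)
  m[1:5, ] <- 1L # 50/100 burnt
  bm <- burn_mask(m, grid_spec(10, 10, 3))
  expect_equal(ground_truth_at_medium(bm, 10, 0.5)$mask[1, 1], 1L)
  m2 <- m; m2[5, 10] <- 0L # 49/100
  bm2 <- burn_mask(m2, grid_spec(10, 10, 3))
  expect_equal(ground_truth_at_medium(bm2, 10, 0.5)$mask[1, 1], 0L)
  # threshold 1 rejects any partially burnt block
  expect_equal(ground_truth_at_medium(bm, 10, 1)$mask[1, 1], 0L)
  expect_error(ground_truth_at_medium(bm, 10, 0), "coverage_threshold")
})

test_that("burnt count is non-increasing in the coverage threshold", {
  set.seed(12)
  m <- matrix(as.integer(runif(900) < 0.4), 30, 30)
  bm <- burn_mask(m, grid_spec(30, 30, 3))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                   function(th) sum(ground_truth_at_medium(bm, 10, th)$mask),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fragmentation increases the number of mixed medium pixels", {
  partial_blocks <- function(frag) {
    cfg <- tiny_config(seed = 77, fragmentation = frag)
    lc <- generate_land_cover(cfg)
    bm <- generate_burn_mask(lc, cfg)
    cov <- crossburn:::block_mean(bm$mask, cfg$factor)
    sum(cov > 0 & cov < 1)
  }
  lo <- partial_blocks(2)
  hi <- partial_blocks(8)
  expect_gt(lo, 0)
  expect_gt(hi, lo)
})

test_that("the full scene pair is reproducible from its config", {
  cfg <- tiny_config(seed = 42)
  p1 <- simulate_scene_pair(cfg)
  p2 <- simulate_scene_pair(cfg)
  expect_identical(p1$vhr$values, p2$vhr$values)
  expect_identical(p1$medium$values, p2$medium$values)
  expect_identical(p1$medium_truth$mask, p2$medium_truth$mask)
})
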