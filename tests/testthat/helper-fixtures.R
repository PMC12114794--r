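# Shared fixtures: everything is generated in code at test time.

# Small paired-scene configuration: 320 x 320 VHR (3 m) -> 32 x 32 medium.
tiny_config <- function(seed = 1L, ...) {
  scene_config(height = 320, width = 320, landcover_smoothness = 12,
               burn_corr_length = 40, seed = seed, ...)
}

# Noise-free, homogeneous-class version (spectrally separable).
tiny_easy_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, vhr_noise_sd = 0, medium_noise_sd = 0,
              spectra = default_spectra(texture = 0), ...)
}

# A constant-reflectance scene.
constant_scene <- function(h = 4, w = 4, value = 0.3,
                           bands = c("Blue", "Green", "Red", "NIR"),
                           pixel_size = 3, origin = c(0, h * pixel_size)) {
  grid <- grid_spec(h, w, pixel_size, origin)
  reflectance_scene(array(value, c(h, w, length(bands))), grid, bands)
}

# A scene whose pixel (i, j) in band b has value (b*100 + (i-1)*w + j) / 1000,
# so every pixel/band is distinct and predictable.
indexed_scene <- function(h = 2, w = 2, bands = c("Blue", "Green", "Red", "NIR"),
                          pixel_size = 1) {
  vals <- array(0, c(h, w, length(bands)))
  for (b in seq_along(bands)) {
    for (i in seq_len(h)) for (j in seq_len(w)) {
      vals[i, j, b] <- (b * 100 + (i - 1) * w + j) / 1000
    }
  }
  reflectance_scene(vals, grid_spec(h, w, pixel_size, c(0, h * pixel_size)),
                    bands)
}

# Minimal all-forest land cover on an arbitrary grid.
forest_landcover <- function(h = 32, w = 32, pixel_size = 10) {
  land_cover_map(matrix(1L, h, w), grid_spec(h, w, pixel_size, c(0, h * pixel_size)),
                 landcover_legend_codes())
}

landcover_legend_codes <- function() {
  c(forest = 1L, water = 2L, road_urban = 3L, barren = 4L)
}

# Fabricated tile set (bypasses extract_tiles) for split/augment tests.
fake_tileset <- function(n, t = 8, seed = 1) {
  set.seed(seed)
  images <- array(runif(n * t * t * 3), c(n, t, t, 3))
  masks <- array(0, c(n, t, t, 2))
  for (k in seq_len(n)) {
    m <- matrix(rbinom(t * t, 1, 0.3), t, t)
    masks[k, , , ] <- one_hot_mask(m)
  }
  structure(
    list(images = images, masks = masks,
         split = factor(rep("train", n), levels = c("train", "test", "validation")),
         provenance = tibble::tibble(tile = seq_len(n), row_off = 0L, col_off = 0L),
         bands = c("NIR", "Red", "Green"), tile_size = as.integer(t),
         stride = as.integer(t), grid = grid_spec(t, t, 30)),
    class = "tile_set"
  )
}

# Tiny architecture for fast training tests: 16 px tiles, 2 blocks.
micro_arch <- function(variant = "unet") {
  architecture_spec(variant, preset = "desk", input_size = 16,
                    encoder_filters = c(3L, 4L), bottleneck_filters = 6L,
                    gru_units = if (variant == "unet_gru") 5L else NULL)
}

# Linearly separable tile set: class decided by a threshold on band 1,
# roughly class-balanced, noise-free.
separable_tileset <- function(n = 12, t = 16, seed = 7) {
  set.seed(seed)
  images <- array(0, c(n, t, t, 3))
  masks <- array(0, c(n, t, t, 2))
  for (k in seq_len(n)) {
    m <- matrix(rbinom(t * t, 1, 0.5), t, t)
    img <- array(0, c(t, t, 3))
    img[, , 1] <- ifelse(m == 1, 0.10, 0.45)
    img[, , 2] <- ifelse(m == 1, 0.03, 0.04)
    img[, , 3] <- ifelse(m == 1, 0.03, 0.06)
    images[k, , , ] <- img
    masks[k, , , ] <- one_hot_mask(m)
  }
  ts <- fake_tileset(n, t)
  ts$images <- images
  ts$masks <- masks
  ts
}
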