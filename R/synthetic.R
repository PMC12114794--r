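#' Per-class reflectance spectrum
#'
#' Describes the mean surface reflectance and within-class texture standard
#' deviation of one land-cover class, per band.
#'
#' @param mean_reflectance Named numeric vector in `[0, 1]`, one per band.
#' @param texture_sd Non-negative per-band standard deviation of within-class
#'   texture. Recycled to the number of bands.
#' @return An object of class `class_spectrum`.
#' @export
class_spectrum <- function(mean_reflectance, texture_sd = 0) {
  stopifnot(all(mean_reflectance >= 0), all(mean_reflectance <= 1))
  texture_sd <- rep_len(texture_sd, length(mean_reflectance))
  if (any(texture_sd < 0)) stop("texture_sd must be >= 0")
  names(texture_sd) <- names(mean_reflectance)
  structure(list(mean = mean_reflectance, sd = texture_sd),
            class = "class_spectrum")
}

#' Default class spectra
#'
#' Plausible surface-reflectance constants for the five surface types the
#' simulator emulates, on the band order Blue, Green, Red, NIR. Burn scars
#' are dark across all bands with strongly depressed NIR relative to healthy
#' forest canopy, so that they read as dark patches in the imagery.
#'
#' @param texture Multiplier on the default within-class texture standard
#'   deviations; `0` gives perfectly homogeneous classes.
#' @return Named list of [class_spectrum()] objects (`forest`, `water`,
#'   `road_urban`, `barren`, `burnt`).
#' @export
default_spectra <- function(texture = 1) {
  bn <- c("Blue", "Green", "Red", "NIR")
  sp <- function(m, s) class_spectrum(stats::setNames(m, bn), texture * s)
  list(
    forest     = sp(c(0.030, 0.060, 0.040, 0.450), 0.015),
    water      = sp(c(0.020, 0.030, 0.020, 0.010), 0.005),
    road_urban = sp(c(0.150, 0.170, 0.180, 0.250), 0.020),
    barren     = sp(c(0.120, 0.150, 0.200, 0.300), 0.020),
    burnt      = sp(c(0.020, 0.030, 0.030, 0.100), 0.008)
  )
}

#' Synthetic scene configuration
#'
#' Parameterises the paired-scene simulator: a very high-resolution (VHR,
#' default 3 m) four-band reflectance scene with burn scars inside forest, a
#' co-registered medium-resolution scene produced by `factor`-fold block
#' aggregation (default 30 m), and a coarser categorical land-cover product
#' (default 10 m).
#'
#' Land cover and scars are drawn from smoothed Gaussian random fields:
#' land-cover classes are quantile bins of one field (so realised class
#' fractions match the requested ones up to resampling), and scars are the
#' top `burn_fraction_target x height x width` forest pixels of an
#' independent field whose correlation length is
#' `burn_corr_length / fragmentation` — larger `fragmentation` gives more,
#' smaller scar components and hence more mixed pixels after aggregation.
#'
#' @param height,width VHR grid dimensions in pixels.
#' @param pixel_size VHR pixel size in metres.
#' @param factor Integer aggregation ratio VHR -> medium (default 10,
#'   i.e. 3 m -> 30 m).
#' @param bands Ordered band names.
#' @param class_fractions Named target area fractions for `forest`, `water`,
#'   `road_urban`, `barren`; must sum to 1, forest > 0.
#' @param spectra Named list of [class_spectrum()] including `burnt`.
#' @param burn_fraction_target Burnt fraction of the *whole scene* (default
#'   0.044, a landscape where scars cover a few percent of the area).
#' @param fragmentation Positive scar-fragmentation control (default 4).
#' @param landcover_smoothness Land-cover field correlation length, VHR px.
#' @param burn_corr_length Base scar-field correlation length, VHR px.
#' @param landcover_pixel_size Pixel size of the exported land-cover map (m).
#' @param vhr_noise_sd,medium_noise_sd Additive Gaussian sensor noise sd.
#' @param coverage_threshold Burnt-coverage fraction at or above which a
#'   medium pixel is ground-truth burnt (default 0.5, majority rule).
#' @param seed Integer seed; all generators are reproducible given it.
#' @param preset Optional shortcut: `"desk"` (the defaults), `"easy"`
#'   (noise-free, homogeneous classes, burn fraction 0.05 — spectrally
#'   separable by construction), or `"full"` (256 px tiles and a larger
#'   scene for full-architecture runs).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 1920, width = 1920, pixel_size = 3,
                         factor = 10,
                         bands = c("Blue", "Green", "Red", "NIR"),
                         class_fractions = c(forest = 0.80, water = 0.05,
                                             road_urban = 0.05, barren = 0.10),
                         spectra = default_spectra(),
                         burn_fraction_target = 0.044,
                         fragmentation = 4,
                         landcover_smoothness = 40,
                         burn_corr_length = 96,
                         landcover_pixel_size = 10,
                         vhr_noise_sd = 0.005,
                         medium_noise_sd = 0.002,
                         coverage_threshold = 0.5,
                         seed = 1L,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "easy", "full"))
    override <- switch(preset,
      desk = list(),
      easy = list(vhr_noise_sd = 0, medium_noise_sd = 0,
                  spectra = default_spectra(texture = 0),
                  burn_fraction_target = 0.05),
      full = list(height = 5120, width = 5120)
    )
    supplied <- setdiff(names(match.call())[-1], c("preset", ""))
    args <- override
    for (nm in supplied) args[[nm]] <- get(nm)
    return(do.call(scene_config, args))
  }
  stopifnot(factor >= 1, burn_fraction_target >= 0, burn_fraction_target < 1,
            vhr_noise_sd >= 0, medium_noise_sd >= 0, fragmentation > 0,
            coverage_threshold > 0, coverage_threshold <= 1)
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1")
  }
  if (!"forest" %in% names(class_fractions) || class_fractions[["forest"]] <= 0) {
    stop("class_fractions must include a positive forest fraction")
  }
  cfg <- list(
    vhr_grid = grid_spec(height, width, pixel_size),
    factor = as.integer(factor),
    bands = bands,
    class_fractions = class_fractions,
    spectra = spectra,
    burn_fraction_target = burn_fraction_target,
    fragmentation = fragmentation,
    landcover_smoothness = landcover_smoothness,
    burn_corr_length = burn_corr_length,
    landcover_pixel_size = landcover_pixel_size,
    vhr_noise_sd = vhr_noise_sd,
    medium_noise_sd = medium_noise_sd,
    coverage_threshold = coverage_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  cfg
}

# Land-cover class codes, fixed across the package.
landcover_legend <- function() {
  c(forest = 1L, water = 2L, road_urban = 3L, barren = 4L)
}

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Smoothed Gaussian random field via FFT convolution with a wrapped
# Gaussian kernel; draws from the current RNG stream.
gaussian_field <- function(height, width, sigma) {
  z <- matrix(stats::rnorm(height * width), height, width)
  if (sigma <= 0) return(z)
  di <- pmin(0:(height - 1), height - (0:(height - 1)))
  dj <- pmin(0:(width - 1), width - (0:(width - 1)))
  k <- exp(-outer(di^2, dj^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (height * width)
}

#' Generate a synthetic land-cover map
#'
#' Draws a smoothed random field on the VHR grid, bins it at the exact
#' quantiles of the requested class fractions (bin order: water, forest,
#' barren, road/urban), and exports the map at the land-cover product's
#' pixel size by nearest-neighbour resampling.
#'
#' @param config A [scene_config()].
#' @return A [land_cover_map()] at `config$landcover_pixel_size` metres.
#' @export
generate_land_cover <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  g <- config$vhr_grid
  legend <- landcover_legend()
  fr <- config$class_fractions
  with_local_seed(config$seed + 101L, {
    field <- gaussian_field(g$height, g$width, config$landcover_smoothness)
    # deterministic bin order keeps water in field lows, built-up in highs
    order_names <- intersect(c("water", "forest", "barren", "road_urban"), names(fr))
    fr <- fr[order_names]
    n <- length(field)
    counts <- round(fr * n)
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    ranks <- rank(field, ties.method = "first")
    cum <- cumsum(counts)
    bin <- findInterval(ranks, c(0, cum), left.open = TRUE)
    classes <- matrix(legend[order_names][bin], g$height, g$width)
    vhr_map <- land_cover_map(classes, g, legend)
    export_grid <- landcover_export_grid(g, config$landcover_pixel_size)
    land_cover_map(resample_nearest(vhr_map$classes, g, export_grid),
                   export_grid, legend)
  })
}

landcover_export_grid <- function(vhr_grid, pixel_size) {
  if (isTRUE(all.equal(pixel_size, vhr_grid$pixel_size))) return(vhr_grid)
  ext_x <- vhr_grid$width * vhr_grid$pixel_size
  ext_y <- vhr_grid$height * vhr_grid$pixel_size
  grid_spec(max(1, round(ext_y / pixel_size)), max(1, round(ext_x / pixel_size)),
            pixel_size, vhr_grid$origin)
}

#' Generate a ground-truth burn mask inside forest
#'
#' Scars are the top `burn_fraction_target * height * width` forest pixels
#' of an independent smoothed random field, so the realised burnt fraction
#' of the scene is exact and scar geometry fragments as
#' `config$fragmentation` grows.
#'
#' @param land_cover A [land_cover_map()] (any grid covering the scene).
#' @param config A [scene_config()].
#' @return A [burn_mask()] on the VHR grid; burnt pixels are a subset of
#'   forest.
#' @export
generate_burn_mask <- function(land_cover, config) {
  stopifnot(inherits(land_cover, "land_cover_map"), inherits(config, "scene_config"))
  g <- config$vhr_grid
  classes <- resample_nearest(land_cover$classes, land_cover$grid, g)
  forest <- classes == land_cover$legend[["forest"]]
  if (!any(forest)) stop("no forest pixels: cannot place burn scars")
  n <- g$height * g$width
  k <- round(config$burn_fraction_target * n)
  if (k == 0) return(burn_mask(matrix(0L, g$height, g$width), g))
  if (k > sum(forest)) {
    stop(sprintf(
      "infeasible burn_fraction_target: %d burnt pixels requested but only %d forest pixels",
      k, sum(forest)
    ))
  }
  with_local_seed(config$seed + 202L, {
    sigma <- config$burn_corr_length / config$fragmentation
    field <- gaussian_field(g$height, g$width, sigma)
    idx <- which(forest)
    sel <- idx[order(field[idx], decreasing = TRUE)[seq_len(k)]]
    m <- matrix(0L, g$height, g$width)
    m[sel] <- 1L
    burn_mask(m, g)
  })
}

#' Render the VHR reflectance scene
#'
#' Per-pixel reflectance is the class mean spectrum (the burnt spectrum
#' where the burn mask is 1), plus per-class Gaussian texture noise and
#' per-band Gaussian sensor noise, clipped to `[0, 1]`.
#'
#' @param land_cover A [land_cover_map()].
#' @param burn A [burn_mask()] on the VHR grid.
#' @param config A [scene_config()].
#' @return A [reflectance_scene()] on the VHR grid.
#' @export
render_vhr_scene <- function(land_cover, burn, config) {
  stopifnot(inherits(land_cover, "land_cover_map"), inherits(burn, "burn_mask"))
  g <- config$vhr_grid
  if (!grids_identical(burn$grid, g)) stop("burn mask grid does not match config VHR grid")
  classes <- resample_nearest(land_cover$classes, land_cover$grid, g)
  legend <- land_cover$legend
  present <- names(legend)[legend %in% unique(as.vector(classes))]
  missing <- setdiff(c(present, if (any(burn$mask == 1L)) "burnt"), names(config$spectra))
  if (length(missing) > 0) {
    stop("no spectrum configured for class(es): ", paste(missing, collapse = ", "))
  }
  check_spectra(config$spectra, config$bands)
  nb <- length(config$bands)
  vals <- array(0, c(g$height, g$width, nb))
  burnt <- burn$mask == 1L
  with_local_seed(config$seed + 303L, {
    for (b in seq_len(nb)) {
      band <- config$bands[b]
      mu <- sd <- rep(0, max(legend))
      for (nm in present) {
        mu[legend[[nm]]] <- config$spectra[[nm]]$mean[[band]]
        sd[legend[[nm]]] <- config$spectra[[nm]]$sd[[band]]
      }
      layer_mu <- matrix(mu[classes], g$height, g$width)
      layer_sd <- matrix(sd[classes], g$height, g$width)
      if (any(burnt)) {
        layer_mu[burnt] <- config$spectra$burnt$mean[[band]]
        layer_sd[burnt] <- config$spectra$burnt$sd[[band]]
      }
      layer <- layer_mu
      if (any(layer_sd > 0)) {
        layer <- layer + stats::rnorm(length(layer)) * layer_sd
      }
      if (config$vhr_noise_sd > 0) {
        layer <- layer + stats::rnorm(length(layer), sd = config$vhr_noise_sd)
      }
      vals[, , b] <- pmin(pmax(layer, 0), 1)
    }
  })
  reflectance_scene(vals, g, config$bands)
}

check_spectra <- function(spectra, bands) {
  for (nm in names(spectra)) {
    sp <- spectra[[nm]]
    if (!all(bands %in% names(sp$mean))) {
      stop("spectrum for class '", nm, "' is missing bands: ",
           paste(setdiff(bands, names(sp$mean)), collapse = ", "))
    }
  }
  if (all(c("forest", "burnt") %in% names(spectra)) && "NIR" %in% bands) {
    if (spectra$burnt$mean[["NIR"]] >= spectra$forest$mean[["NIR"]]) {
      stop("burnt spectrum must have lower NIR than forest (scars are dark patches)")
    }
  }
  invisible(TRUE)
}

# Crop an array/matrix to the largest factor-divisible extent (top-left anchored).
crop_divisible <- function(x, factor) {
  d <- dim(x)
  h <- (d[1] %/% factor) * factor
  w <- (d[2] %/% factor) * factor
  if (h == 0 || w == 0) stop("grid smaller than the aggregation factor")
  if (length(d) == 2) x[seq_len(h), seq_len(w), drop = FALSE]
  else x[seq_len(h), seq_len(w), , drop = FALSE]
}

# factor x factor block mean of a matrix (dims must divide).
block_mean <- function(x, factor) {
  h <- nrow(x); w <- ncol(x)
  s1 <- colMeans(array(x, c(factor, h %/% factor, w)))      # (h/f) x w
  t(colMeans(array(t(s1), c(factor, w %/% factor, h %/% factor))))
}

block_sum <- function(x, factor) block_mean(x, factor) * factor^2

#' Aggregate a VHR scene to medium resolution
#'
#' Each medium pixel is the arithmetic mean of its `factor x factor` VHR
#' block per band (no point-spread function), plus optional Gaussian sensor
#' noise, clipped to `[0, 1]`. The scene is cropped to the largest
#' factor-divisible extent first.
#'
#' @param vhr A [reflectance_scene()].
#' @param factor Integer aggregation ratio (>= 1).
#' @param sensor_noise_sd Per-band (recycled) additive noise sd; default 0.
#' @param seed Optional seed for the noise draw.
#' @return A [reflectance_scene()] with `pixel_size = factor * vhr pixel`.
#' @export
degrade_to_medium <- function(vhr, factor, sensor_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(vhr, "reflectance_scene"))
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  factor <- as.integer(factor)
  vals <- crop_divisible(vhr$values, factor)
  h <- dim(vals)[1] %/% factor
  w <- dim(vals)[2] %/% factor
  nb <- dim(vals)[3]
  out <- array(0, c(h, w, nb))
  for (b in seq_len(nb)) out[, , b] <- block_mean(vals[, , b], factor)
  sds <- rep_len(sensor_noise_sd, nb)
  if (any(sds > 0)) {
    noisy <- function() {
      for (b in seq_len(nb)) {
        if (sds[b] > 0) out[, , b] <<- out[, , b] + stats::rnorm(h * w, sd = sds[b])
      }
    }
    if (is.null(seed)) noisy() else with_local_seed(seed, noisy())
    out <- pmin(pmax(out, 0), 1)
    out <- array(out, c(h, w, nb))
  }
  grid <- grid_spec(h, w, vhr$grid$pixel_size * factor, vhr$grid$origin)
  reflectance_scene(out, grid, vhr$bands)
}

#' Transfer a fine-grid binary mask to the coarse grid by burnt coverage
#'
#' A medium pixel is burnt iff the fraction of burnt VHR pixels in its
#' `factor x factor` block is at least `coverage_threshold`.
#'
#' @param vhr_mask A [burn_mask()] on the fine grid.
#' @param factor Integer aggregation ratio (>= 1).
#' @param coverage_threshold Fraction in `(0, 1]`; default 0.5 (majority).
#' @return A [burn_mask()] on the coarse grid.
#' @export
ground_truth_at_medium <- function(vhr_mask, factor, coverage_threshold = 0.5) {
  stopifnot(inherits(vhr_mask, "burn_mask"))
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  if (coverage_threshold <= 0 || coverage_threshold > 1) {
    stop("coverage_threshold must be in (0, 1]")
  }
  factor <- as.integer(factor)
  m <- crop_divisible(vhr_mask$mask, factor)
  cov <- block_mean(m, factor)
  out <- matrix(0L, nrow(cov), ncol(cov))
  # tolerance keeps exact block fractions (k/f^2) stable under fp division
  out[cov >= coverage_threshold - 1e-12] <- 1L
  grid <- grid_spec(nrow(cov), ncol(cov), vhr_mask$grid$pixel_size * factor,
                    vhr_mask$grid$origin)
  burn_mask(out, grid)
}

#' Simulate a co-registered VHR / medium scene pair
#'
#' Convenience wrapper running the whole generator chain: land cover, VHR
#' ground-truth scars, VHR reflectance, block-aggregated medium reflectance,
#' and the medium-grid ground truth under the configured coverage threshold.
#'
#' @param config A [scene_config()].
#' @return A list of class `scene_pair` with elements `land_cover`,
#'   `vhr_truth`, `vhr`, `medium`, `medium_truth`, `forest_vhr`,
#'   `forest_medium`, and `config`.
#' @export
simulate_scene_pair <- function(config) {
  lc <- generate_land_cover(config)
  truth <- generate_burn_mask(lc, config)
  vhr <- render_vhr_scene(lc, truth, config)
  med <- degrade_to_medium(vhr, config$factor, config$medium_noise_sd,
                           seed = config$seed + 404L)
  med_truth <- ground_truth_at_medium(truth, config$factor, config$coverage_threshold)
  forest_codes <- landcover_legend()[["forest"]]
  fv <- build_forest_mask(lc, forest_codes, vhr$grid)
  fm <- build_forest_mask(lc, forest_codes, med$grid)
  structure(
    list(land_cover = lc, vhr_truth = truth, vhr = vhr, medium = med,
         medium_truth = med_truth, forest_vhr = fv, forest_medium = fm,
         config = config),
    class = "scene_pair"
  )
}
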