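#' Build a binary forest mask from a land-cover map
#'
#' Resamples the categorical land-cover map to the target grid by nearest
#' neighbour (categorical data must not be averaged) and marks pixels whose
#' class code belongs to `forest_codes`. Non-forest classes — water, roads,
#' urban, barren — are thereby excluded from labelling and evaluation.
#'
#' @param land_cover A [land_cover_map()].
#' @param forest_codes Integer class codes counting as forest; must be a
#'   non-empty subset of the map legend.
#' @param target_grid A [grid_spec()] covering the same extent; defaults to
#'   the land-cover grid.
#' @return A [forest_mask()] on `target_grid`.
#' @export
build_forest_mask <- function(land_cover, forest_codes,
                              target_grid = land_cover$grid) {
  stopifnot(inherits(land_cover, "land_cover_map"))
  if (length(forest_codes) == 0) stop("forest_codes must be non-empty")
  if (!all(forest_codes %in% land_cover$legend)) {
    stop("forest_codes not in land-cover legend: ",
         paste(setdiff(forest_codes, land_cover$legend), collapse = ", "))
  }
  classes <- resample_nearest(land_cover$classes, land_cover$grid, target_grid)
  m <- matrix(0L, target_grid$height, target_grid$width)
  m[classes %in% forest_codes] <- 1L
  forest_mask(m, target_grid)
}

#' Sample raster values at point locations
#'
#' Reads per-band reflectance from the pixel containing each point (no
#' interpolation; pixel extents are half-open, see [grid_spec()]).
#'
#' @param scene A [reflectance_scene()].
#' @param points A data frame with numeric columns `x` and `y` (map
#'   coordinates), or a two-column matrix.
#' @return A `point_sample_set`: tibble with columns `x`, `y` and one column
#'   per band, plus attributes `bands`.
#' @export
sample_raster_values <- function(scene, points) {
  stopifnot(inherits(scene, "reflectance_scene"))
  points <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(points))) {
    colnames(points)[1:2] <- c("x", "y")
  }
  if (nrow(points) == 0) stop("points must be non-empty")
  loc <- locate_points(scene$grid, points$x, points$y)
  if (any(!loc$inside)) {
    bad <- which(!loc$inside)[1]
    stop(sprintf("point (%g, %g) falls outside the raster extent",
                 points$x[bad], points$y[bad]))
  }
  out <- tibble::tibble(x = points$x, y = points$y)
  for (b in seq_along(scene$bands)) {
    layer <- scene$values[, , b]
    out[[scene$bands[b]]] <- layer[cbind(loc$row, loc$col)]
  }
  attr(out, "bands") <- scene$bands
  class(out) <- c("point_sample_set", class(out))
  out
}

#' Per-band minimum and maximum over a sample set
#'
#' The min/max ranges of the sampled burnt pixels define the multi-band
#' threshold classifier: a pixel is called burnt when every band falls
#' inside its sampled range.
#'
#' @param samples A `point_sample_set` from [sample_raster_values()], or any
#'   data frame whose band columns are named in `attr(., "bands")` /
#'   `bands`.
#' @param bands Bands to range over; defaults to all sampled bands.
#' @return A `band_ranges` tibble with columns `band`, `min`, `max`.
#' @export
compute_band_ranges <- function(samples, bands = NULL) {
  if (is.null(bands)) bands <- attr(samples, "bands")
  if (is.null(bands)) bands <- setdiff(names(samples), c("x", "y"))
  if (nrow(samples) == 0) stop("cannot compute ranges from an empty sample set")
  out <- tibble::tibble(
    band = bands,
    min = unname(vapply(bands, function(b) min(samples[[b]]), numeric(1))),
    max = unname(vapply(bands, function(b) max(samples[[b]]), numeric(1)))
  )
  class(out) <- c("band_ranges", class(out))
  out
}

#' Multi-band min/max threshold classification
#'
#' A pixel is labelled burnt iff it is forest and, for every thresholded
#' band, its reflectance lies inside that band's `[min, max]` range
#' (conjunction across bands, inclusive bounds).
#'
#' @param scene A [reflectance_scene()].
#' @param ranges A `band_ranges` tibble ([compute_band_ranges()]); may cover
#'   a subset of the scene's bands.
#' @param forest A [forest_mask()] on the scene grid.
#' @return A [burn_mask()] on the scene grid.
#' @export
threshold_classify <- function(scene, ranges, forest) {
  stopifnot(inherits(scene, "reflectance_scene"), inherits(forest, "forest_mask"))
  if (!grids_identical(scene$grid, forest$grid)) {
    stop("scene and forest mask must share a grid")
  }
  missing <- setdiff(ranges$band, scene$bands)
  if (length(missing) > 0) {
    stop("ranges refer to bands absent from the scene: ",
         paste(missing, collapse = ", "))
  }
  inside <- forest$mask == 1L
  for (i in seq_len(nrow(ranges))) {
    b <- match(ranges$band[i], scene$bands)
    layer <- scene$values[, , b]
    inside <- inside & layer >= ranges$min[i] & layer <= ranges$max[i]
  }
  m <- matrix(0L, scene$grid$height, scene$grid$width)
  m[inside] <- 1L
  burn_mask(m, scene$grid)
}

#' Project fine-grid labels onto the coarse grid
#'
#' Identical semantics to [ground_truth_at_medium()] (shared
#' implementation): a coarse pixel is burnt iff the burnt coverage of its
#' `factor x factor` fine block meets `coverage_threshold`.
#'
#' @inheritParams ground_truth_at_medium
#' @param vhr_labels A [burn_mask()] of fine-grid labels.
#' @return A [burn_mask()] on the coarse grid.
#' @export
transfer_labels <- function(vhr_labels, factor, coverage_threshold = 0.5) {
  ground_truth_at_medium(vhr_labels, factor, coverage_threshold)
}

#' Draw sample points from homogeneous burnt regions
#'
#' Emulates field sampling over clear, homogeneous scars: candidate pixels
#' are burnt pixels whose 4-neighbours are all burnt (interior pixels) when
#' enough exist, otherwise any burnt pixel; `n` of them are drawn without
#' replacement and returned as pixel-centre map coordinates.
#'
#' @param mask A [burn_mask()] of the regions to sample.
#' @param n Number of points.
#' @param seed Integer seed.
#' @param interior_only Prefer interior (fully surrounded) pixels; default
#'   TRUE.
#' @return Tibble with columns `x`, `y`.
#' @export
sample_points_from_mask <- function(mask, n, seed = 1L, interior_only = TRUE) {
  stopifnot(inherits(mask, "burn_mask"), n >= 1)
  m <- mask$mask
  cand <- m == 1L
  if (interior_only) {
    h <- nrow(m); w <- ncol(m)
    pad <- matrix(0L, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- m
    interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
      pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)] & m
    if (sum(interior) >= n) cand <- interior == 1L
  }
  idx <- which(cand)
  if (length(idx) == 0) stop("mask has no pixels to sample")
  with_local_seed(seed, {
    take <- if (length(idx) <= n) idx else sample(idx, n)
    rows <- ((take - 1) %% nrow(m)) + 1
    cols <- ((take - 1) %/% nrow(m)) + 1
    ctr <- pixel_centres(mask$grid)
    tibble::tibble(x = ctr$x[cols], y = ctr$y[rows])
  })
}
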