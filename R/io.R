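#' Write a reflectance scene to TIFF with a georeferencing sidecar
#'
#' Reflectance is written as 32-bit float TIFF (one file, multi-channel);
#' the grid metadata (pixel size, origin, band names) goes to a JSON sidecar
#' `<path>.json`, since plain TIFF carries no georeferencing.
#'
#' @param scene A [reflectance_scene()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  stopifnot(inherits(scene, "reflectance_scene"))
  tiff::writeTIFF(scene$values, path, bits.per.sample = 32)
  sidecar <- list(
    kind = "reflectance_scene",
    height = scene$grid$height, width = scene$grid$width,
    pixel_size = scene$grid$pixel_size, origin = scene$grid$origin,
    bands = scene$bands
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a reflectance scene written by [write_scene_tiff()]
#'
#' @param path Path to the `.tif` file (sidecar `<path>.json` must exist).
#' @return A [reflectance_scene()].
#' @export
read_scene_tiff <- function(path) {
  # 4-band imagery trips libtiff's alpha-channel heuristic; the samples are
  # plain spectral bands, so the warning is spurious
  vals <- suppressWarnings(tiff::readTIFF(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$height, meta$width, meta$pixel_size, meta$origin)
  reflectance_scene(vals, grid, meta$bands)
}

#' Write a binary mask to an 8-bit TIFF with sidecar
#'
#' Mask values are stored as 0/1 in an 8-bit channel.
#'
#' @param mask A [burn_mask()] or [forest_mask()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "burn_mask") || inherits(mask, "forest_mask"))
  tiff::writeTIFF(mask$mask / 255, path, bits.per.sample = 8)
  sidecar <- list(
    kind = class(mask)[1],
    height = mask$grid$height, width = mask$grid$width,
    pixel_size = mask$grid$pixel_size, origin = mask$grid$origin
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a mask written by [write_mask_tiff()]
#'
#' @param path Path to the `.tif` file.
#' @return A [burn_mask()] (or [forest_mask()] if written from one).
#' @export
read_mask_tiff <- function(path) {
  vals <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$height, meta$width, meta$pixel_size, meta$origin)
  m <- matrix(as.integer(round(vals * 255)), nrow(vals), ncol(vals))
  if (identical(meta$kind, "forest_mask")) forest_mask(m, grid)
  else burn_mask(m, grid)
}

#' Write a land-cover map to an 8-bit TIFF with a legend sidecar
#'
#' @param land_cover A [land_cover_map()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_landcover_tiff <- function(land_cover, path) {
  stopifnot(inherits(land_cover, "land_cover_map"))
  tiff::writeTIFF(land_cover$classes / 255, path, bits.per.sample = 8)
  sidecar <- list(
    kind = "land_cover_map",
    height = land_cover$grid$height, width = land_cover$grid$width,
    pixel_size = land_cover$grid$pixel_size, origin = land_cover$grid$origin,
    legend = as.list(land_cover$legend)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a land-cover map written by [write_landcover_tiff()]
#'
#' @param path Path to the `.tif` file.
#' @return A [land_cover_map()].
#' @export
read_landcover_tiff <- function(path) {
  vals <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$height, meta$width, meta$pixel_size, meta$origin)
  classes <- matrix(as.integer(round(vals * 255)), nrow(vals), ncol(vals))
  land_cover_map(classes, grid, unlist(meta$legend))
}

#' Read sample points from CSV or GeoJSON
#'
#' CSV files need `x` and `y` columns; GeoJSON files must contain Point
#' features (a FeatureCollection, a bare geometry, or a list of either).
#'
#' @param path Path to a `.csv`, `.geojson` or `.json` file.
#' @return Tibble with columns `x`, `y`.
#' @export
read_points <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    pts <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("x", "y") %in% names(pts))) {
      stop("CSV point files must have columns 'x' and 'y'")
    }
    return(tibble::tibble(x = pts$x, y = pts$y))
  }
  gj <- jsonlite::read_json(path)
  coords <- geojson_point_coords(gj)
  if (length(coords) == 0) stop("no Point features found in ", path)
  tibble::tibble(
    x = vapply(coords, function(c) as.numeric(c[[1]]), numeric(1)),
    y = vapply(coords, function(c) as.numeric(c[[2]]), numeric(1))
  )
}

geojson_point_coords <- function(node) {
  if (is.list(node) && identical(node$type, "FeatureCollection")) {
    return(do.call(c, lapply(node$features, geojson_point_coords)))
  }
  if (is.list(node) && identical(node$type, "Feature")) {
    return(geojson_point_coords(node$geometry))
  }
  if (is.list(node) && identical(node$type, "Point")) {
    return(list(node$coordinates))
  }
  if (is.list(node) && is.null(node$type)) {
    return(do.call(c, lapply(node, geojson_point_coords)))
  }
  list()
}

#' Serialize band ranges to JSON
#'
#' @param ranges A `band_ranges` tibble ([compute_band_ranges()]).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ranges_json <- function(ranges, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(ranges)), function(i) {
      list(band = ranges$band[i], min = ranges$min[i], max = ranges$max[i])
    }),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read band ranges written by [write_ranges_json()]
#'
#' @param path Path to the `.json` file.
#' @return A `band_ranges` tibble.
#' @export
read_ranges_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::tibble(band = lst$band, min = lst$min, max = lst$max)
  class(out) <- c("band_ranges", class(out))
  out
}
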