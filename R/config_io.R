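#' Read a scene configuration from a structured text file
#'
#' The file is YAML with top-level keys matching [scene_config()] arguments
#' (`height`, `width`, `factor`, `burn_fraction_target`, ...), an optional
#' `preset`, an optional `class_fractions` mapping, and an optional
#' `spectra` section of per-class `mean`/`sd` mappings keyed by band name:
#'
#' ```yaml
#' preset: desk
#' burn_fraction_target: 0.044
#' class_fractions: {forest: 0.8, water: 0.05, road_urban: 0.05, barren: 0.1}
#' spectra:
#'   burnt:
#'     mean: {Blue: 0.02, Green: 0.03, Red: 0.03, NIR: 0.10}
#'     sd: 0.008
#' ```
#'
#' Classes absent from `spectra` keep their defaults.
#'
#' @param path Path to the YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$class_fractions)) {
    args$class_fractions <- unlist(raw$class_fractions)
  }
  if (!is.null(raw$spectra)) {
    spectra <- default_spectra()
    for (nm in names(raw$spectra)) {
      sp <- raw$spectra[[nm]]
      m <- unlist(sp$mean)
      s <- if (is.null(sp$sd)) 0 else unlist(sp$sd)
      spectra[[nm]] <- class_spectrum(m, s)
    }
    args$spectra <- spectra
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(scene_config, args)
}

#' Save a trained model to disk
#'
#' Weights and caches are serialized as RDS next to a JSON sidecar holding
#' the architecture spec, best epoch and training history.
#'
#' @param model A `segmentation_model`.
#' @param path Output path (`.rds`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "segmentation_model"))
  saveRDS(model, path)
  side <- list(
    variant = model$spec$variant,
    input_size = model$spec$input_size,
    encoder_filters = model$spec$encoder_filters,
    bottleneck_filters = model$spec$bottleneck_filters,
    gru_units = model$spec$gru_units,
    n_params = count_params(model),
    best_epoch = model$best_epoch
  )
  if (!is.null(model$history)) side$history <- model$history
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the `.rds` file.
#' @return A `segmentation_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "segmentation_model"))
  model
}

#' Persist a tile set as per-tile TIFFs with a CSV manifest
#'
#' Each tile is written as a float TIFF (bands as channels) with its mask as
#' an 8-bit TIFF; `manifest.csv` records tile id, offsets and split.
#'
#' @param tiles A `tile_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tile_set <- function(tiles, dir) {
  stopifnot(inherits(tiles, "tile_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(tiles$images)[1]
  ts <- tiles$tile_size
  for (k in seq_len(n)) {
    tiff::writeTIFF(array(tiles$images[k, , , ], c(ts, ts, dim(tiles$images)[4])),
                    file.path(dir, sprintf("tile_%04d.tif", k)),
                    bits.per.sample = 32)
    m <- collapse_one_hot(array(tiles$masks[k, , , ], c(ts, ts, 2)))
    tiff::writeTIFF(m / 255, file.path(dir, sprintf("mask_%04d.tif", k)),
                    bits.per.sample = 8)
  }
  manifest <- tiles$provenance
  manifest$split <- as.character(tiles$split)
  manifest$tile_size <- ts
  manifest$bands <- paste(tiles$bands, collapse = ",")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Load a tile set written by [write_tile_set()]
#'
#' @param dir Directory containing the tiles and `manifest.csv`.
#' @return A `tile_set`.
#' @export
read_tile_set <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  n <- nrow(manifest)
  ts <- manifest$tile_size[1]
  bands <- strsplit(manifest$bands[1], ",")[[1]]
  images <- array(0, c(n, ts, ts, length(bands)))
  masks <- array(0, c(n, ts, ts, 2))
  for (k in seq_len(n)) {
    img <- suppressWarnings(tiff::readTIFF(file.path(dir, sprintf("tile_%04d.tif", k))))
    images[k, , , ] <- img
    m <- tiff::readTIFF(file.path(dir, sprintf("mask_%04d.tif", k)))
    masks[k, , , ] <- one_hot_mask(matrix(as.integer(round(m * 255)),
                                          nrow(m), ncol(m)))
  }
  structure(
    list(images = images, masks = masks,
         split = factor(manifest$split, levels = c("train", "test", "validation")),
         provenance = manifest[c("tile", "row_off", "col_off")],
         bands = bands, tile_size = as.integer(ts), stride = as.integer(ts),
         grid = grid_spec(ts, ts, 30)),
    class = "tile_set"
  )
}
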