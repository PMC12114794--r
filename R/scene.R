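#' Multiband reflectance scene
#'
#' Wraps a `height x width x n_bands` array of surface reflectance in
#' `[0, 1]` together with its [grid_spec()] and ordered band names.
#'
#' @param values Numeric array `height x width x n_bands`, finite, in `[0, 1]`.
#' @param grid A [grid_spec()] matching the array's first two dimensions.
#' @param bands Character vector of band names, one per array slice.
#'
#' @return An object of class `reflectance_scene`.
#' @export
reflectance_scene <- function(values, grid, bands) {
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3)
  if (dim(values)[1] != grid$height || dim(values)[2] != grid$width) {
    stop("values shape does not match grid")
  }
  if (dim(values)[3] != length(bands)) {
    stop("number of array slices does not match band list")
  }
  if (!all(is.finite(values))) stop("reflectance values must be finite")
  dimnames(values) <- NULL
  structure(
    list(grid = grid, bands = as.character(bands), values = values),
    class = "reflectance_scene"
  )
}

#' @export
print.reflectance_scene <- function(x, ...) {
  cat(sprintf(
    "<reflectance_scene> %d x %d @ %g m, bands: %s\n",
    x$grid$height, x$grid$width, x$grid$pixel_size,
    paste(x$bands, collapse = ", ")
  ))
  invisible(x)
}

#' Categorical land-cover map
#'
#' @param classes Integer matrix of class codes, `height x width`.
#' @param grid A [grid_spec()].
#' @param legend Named integer vector mapping class names (e.g. `"forest"`)
#'   to codes; every code present in `classes` must appear in the legend.
#'
#' @return An object of class `land_cover_map`.
#' @export
land_cover_map <- function(classes, grid, legend) {
  stopifnot(is.matrix(classes), nrow(classes) == grid$height, ncol(classes) == grid$width)
  stopifnot(!is.null(names(legend)), !anyDuplicated(names(legend)))
  present <- sort(unique(as.vector(classes)))
  if (!all(present %in% legend)) {
    stop("class codes present in the map but missing from the legend: ",
         paste(setdiff(present, legend), collapse = ", "))
  }
  structure(
    list(grid = grid, classes = classes, legend = legend),
    class = "land_cover_map"
  )
}

#' @export
print.land_cover_map <- function(x, ...) {
  tab <- table(factor(x$classes, levels = x$legend, labels = names(x$legend)))
  frac <- round(100 * as.numeric(tab) / sum(tab), 1)
  cat(sprintf("<land_cover_map> %d x %d @ %g m\n", x$grid$height, x$grid$width,
              x$grid$pixel_size))
  cat(paste(sprintf("  %s: %s%%", names(tab), frac), collapse = "\n"), "\n")
  invisible(x)
}

#' Binary burnt-area mask
#'
#' @param mask Matrix of 0/1 values (1 = burnt) on `grid`.
#' @param grid A [grid_spec()].
#'
#' @return An object of class `burn_mask`.
#' @export
burn_mask <- function(mask, grid) {
  stopifnot(is.matrix(mask), nrow(mask) == grid$height, ncol(mask) == grid$width)
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0 or 1")
  storage.mode(mask) <- "integer"
  structure(list(grid = grid, mask = mask), class = "burn_mask")
}

#' @export
print.burn_mask <- function(x, ...) {
  n <- sum(x$mask)
  tot <- length(x$mask)
  cat(sprintf(
    "<burn_mask> %d x %d @ %g m; burnt: %d px (%.2f%%)\n",
    x$grid$height, x$grid$width, x$grid$pixel_size, n, 100 * n / tot
  ))
  invisible(x)
}

#' Binary forest mask
#'
#' @param mask Matrix of 0/1 values (1 = forest) on `grid`.
#' @param grid A [grid_spec()].
#' @return An object of class `forest_mask`.
#' @export
forest_mask <- function(mask, grid) {
  stopifnot(is.matrix(mask), nrow(mask) == grid$height, ncol(mask) == grid$width)
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0 or 1")
  storage.mode(mask) <- "integer"
  structure(list(grid = grid, mask = mask), class = "forest_mask")
}

#' @export
print.forest_mask <- function(x, ...) {
  cat(sprintf(
    "<forest_mask> %d x %d @ %g m; forest: %.1f%%\n",
    x$grid$height, x$grid$width, x$grid$pixel_size, 100 * mean(x$mask)
  ))
  invisible(x)
}
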