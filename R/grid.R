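#' Raster grid specification
#'
#' A `grid_spec` describes a regular raster grid: its dimensions in pixels,
#' the ground size of a pixel in metres, and the map coordinate of the
#' top-left corner. Rows run top to bottom (decreasing y), columns left to
#' right (increasing x). Pixel `(i, j)` covers the half-open ground extent
#' `[x0 + (j-1)s, x0 + js)` in x and `(y0 - is, y0 - (i-1)s]` in y, where
#' `s` is the pixel size.
#'
#' @param height,width Grid dimensions in pixels (positive integers).
#' @param pixel_size Ground size of one pixel in metres (> 0).
#' @param origin Numeric length-2: map `(x, y)` of the top-left grid corner.
#'
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(100, 100, pixel_size = 3)
grid_spec <- function(height, width, pixel_size, origin = c(0, 0)) {
  stopifnot(
    length(height) == 1, length(width) == 1, length(pixel_size) == 1,
    is.finite(height), is.finite(width), is.finite(pixel_size),
    length(origin) == 2, all(is.finite(origin))
  )
  if (height < 1 || width < 1) {
    stop("grid must have positive dimensions (zero-area grids are invalid)")
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      pixel_size = as.numeric(pixel_size), origin = as.numeric(origin)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d pixels @ %g m, origin (%g, %g)\n",
    x$height, x$width, x$pixel_size, x$origin[1], x$origin[2]
  ))
  invisible(x)
}

grid_extent <- function(grid) {
  list(
    xmin = grid$origin[1],
    xmax = grid$origin[1] + grid$width * grid$pixel_size,
    ymax = grid$origin[2],
    ymin = grid$origin[2] - grid$height * grid$pixel_size
  )
}

grids_identical <- function(a, b) {
  a$height == b$height && a$width == b$width &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Map coordinates of pixel centres
#'
#' @param grid A [grid_spec()].
#' @return A list with numeric vectors `x` (length `width`) and `y`
#'   (length `height`) of pixel-centre coordinates.
#' @export
pixel_centres <- function(grid) {
  s <- grid$pixel_size
  list(
    x = grid$origin[1] + (seq_len(grid$width) - 0.5) * s,
    y = grid$origin[2] - (seq_len(grid$height) - 0.5) * s
  )
}

# Row/column of the pixel containing each (x, y) point, half-open convention.
# Returns a list(row, col, inside).
locate_points <- function(grid, x, y) {
  s <- grid$pixel_size
  col <- floor((x - grid$origin[1]) / s) + 1
  row <- floor((grid$origin[2] - y) / s) + 1
  # top edge (y == y0) belongs to row 1; left edge handled by floor already
  row[y == grid$origin[2]] <- 1L
  inside <- col >= 1 & col <= grid$width & row >= 1 & row <= grid$height
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

# Nearest-neighbour resampling of a categorical (or any) matrix from one grid
# to another covering the same map extent: each target pixel takes the value
# of the source pixel containing its centre.
resample_nearest <- function(values, src_grid, dst_grid) {
  stopifnot(nrow(values) == src_grid$height, ncol(values) == src_grid$width)
  centres <- pixel_centres(dst_grid)
  loc_col <- locate_points(src_grid, centres$x, rep(src_grid$origin[2], length(centres$x)))$col
  loc_row <- locate_points(src_grid, rep(src_grid$origin[1], length(centres$y)), centres$y)$row
  loc_col <- pmin(pmax(loc_col, 1L), src_grid$width)
  loc_row <- pmin(pmax(loc_row, 1L), src_grid$height)
  values[loc_row, loc_col, drop = FALSE]
}
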