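#' One-hot encode a binary mask
#'
#' @param mask 0/1 matrix.
#' @return Array `h x w x 2`; channel 1 = unburnt, channel 2 = burnt.
#' @export
one_hot_mask <- function(mask) {
  out <- array(0, c(nrow(mask), ncol(mask), 2))
  out[, , 1] <- 1 - mask
  out[, , 2] <- mask
  out
}

#' Collapse a one-hot mask back to class labels
#'
#' Per-pixel argmax over the class channels, ties broken toward the lowest
#' class index (class 0, unburnt).
#'
#' @param oh Array `h x w x 2`.
#' @return 0/1 integer matrix.
#' @export
collapse_one_hot <- function(oh) {
  m <- matrix(0L, dim(oh)[1], dim(oh)[2])
  m[oh[, , 2] > oh[, , 1]] <- 1L
  m
}

#' Cut a scene and its labels into fixed-size training tiles
#'
#' Tiles are taken on a regular grid with the given stride, with any
#' remainder at the right/bottom edge dropped. Image bands are reordered to
#' (NIR, Red, Green) — the three-band input the segmentation networks take —
#' and labels are one-hot encoded.
#'
#' @param scene A [reflectance_scene()] containing at least the NIR, Red and
#'   Green bands.
#' @param labels A [burn_mask()] co-registered with `scene`.
#' @param tile_size Tile edge in pixels (default 256).
#' @param stride Tile grid step (default `tile_size`, non-overlapping).
#' @param bands Bands to stack, in output order.
#' @return A `tile_set`: list with `images` (`N x t x t x 3`), `masks`
#'   (`N x t x t x 2`), `split` (factor, initially all `"train"`), and
#'   `provenance` (tibble: `tile`, `row_off`, `col_off`).
#' @export
extract_tiles <- function(scene, labels, tile_size = 256, stride = tile_size,
                          bands = c("NIR", "Red", "Green")) {
  stopifnot(inherits(scene, "reflectance_scene"), inherits(labels, "burn_mask"))
  if (!grids_identical(scene$grid, labels$grid)) {
    stop("scene and labels must be co-registered")
  }
  h <- scene$grid$height; w <- scene$grid$width
  if (tile_size > h || tile_size > w) stop("tile_size exceeds scene dimensions")
  if (!all(bands %in% scene$bands)) {
    stop("scene lacks required bands: ",
         paste(setdiff(bands, scene$bands), collapse = ", "))
  }
  bidx <- match(bands, scene$bands)
  row_off <- seq(0, h - tile_size, by = stride)
  col_off <- seq(0, w - tile_size, by = stride)
  offs <- expand.grid(row_off = row_off, col_off = col_off)
  offs <- offs[order(offs$row_off, offs$col_off), , drop = FALSE]
  n <- nrow(offs)
  images <- array(0, c(n, tile_size, tile_size, length(bands)))
  masks <- array(0, c(n, tile_size, tile_size, 2))
  for (k in seq_len(n)) {
    ri <- offs$row_off[k] + seq_len(tile_size)
    ci <- offs$col_off[k] + seq_len(tile_size)
    images[k, , , ] <- scene$values[ri, ci, bidx]
    masks[k, , , ] <- one_hot_mask(labels$mask[ri, ci])
  }
  structure(
    list(
      images = images, masks = masks,
      split = factor(rep("train", n), levels = c("train", "test", "validation")),
      provenance = tibble::tibble(tile = seq_len(n),
                                  row_off = offs$row_off, col_off = offs$col_off),
      bands = bands, tile_size = as.integer(tile_size),
      stride = as.integer(stride), grid = scene$grid
    ),
    class = "tile_set"
  )
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d tiles of %d x %d (%s); splits: %s\n",
              dim(x$images)[1], x$tile_size, x$tile_size,
              paste(x$bands, collapse = ","),
              paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                    collapse = " ")))
  invisible(x)
}

#' Assign train/test/validation splits
#'
#' Randomly (seeded) partitions tiles into disjoint, exhaustive splits given
#' either exact counts or fractions.
#'
#' @param tiles A `tile_set`.
#' @param counts Named integer vector `c(train=, test=, validation=)`
#'   summing to the tile count, or `NULL` to use `fractions`.
#' @param fractions Named fractions summing to 1 (used when `counts` is
#'   `NULL`); counts are rounded with the remainder going to `train`.
#' @param seed Integer seed for the permutation.
#' @return The `tile_set` with its `split` field assigned.
#' @export
assign_splits <- function(tiles, counts = NULL,
                          fractions = c(train = 0.75, test = 0.125,
                                        validation = 0.125),
                          seed = 1L) {
  stopifnot(inherits(tiles, "tile_set"))
  n <- dim(tiles$images)[1]
  lv <- c("train", "test", "validation")
  if (is.null(counts)) {
    stopifnot(abs(sum(fractions) - 1) < 1e-8)
    fractions <- fractions[lv]
    fractions[is.na(fractions)] <- 0
    counts <- round(fractions * n)
    counts["train"] <- n - sum(counts[c("test", "validation")])
    names(counts) <- lv
  } else {
    if (is.null(names(counts))) names(counts) <- lv[seq_along(counts)]
    counts <- counts[lv]
    counts[is.na(counts)] <- 0
    names(counts) <- lv
  }
  if (any(counts < 0) || sum(counts) != n) {
    stop(sprintf("split counts (%s) must be non-negative and sum to %d",
                 paste(counts, collapse = ", "), n))
  }
  with_local_seed(seed, {
    perm <- sample.int(n)
    lab <- rep(lv, times = counts)
    tiles$split <- factor(lab[order(perm)], levels = lv)
  })
  tiles$provenance$split <- tiles$split
  tiles
}

# The 8 dihedral transforms of a square tile; each acts identically on every
# channel, so applying the same index to image and mask keeps them aligned.
dihedral_apply <- function(x, transform) {
  # x: h x w x c array
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  f <- switch(transform,
    identity = function(m) m,
    hflip = function(m) m[, ncol(m):1, drop = FALSE],
    vflip = function(m) m[nrow(m):1, , drop = FALSE],
    rot90 = rot90,
    rot180 = function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = function(m) rot90(rot90(rot90(m))),
    transpose = function(m) t(m),
    antitranspose = function(m) t(m[nrow(m):1, ncol(m):1, drop = FALSE]),
    stop("unknown transform: ", transform)
  )
  out <- array(0, dim(x))
  for (c in seq_len(dim(x)[3])) out[, , c] <- f(x[, , c])
  out
}

dihedral_transforms <- function() {
  c("identity", "hflip", "vflip", "rot90", "rot180", "rot270",
    "transpose", "antitranspose")
}

#' Augment paired image/mask batches with rigid transforms
#'
#' Applies one randomly chosen dihedral transform (identity, flips, 90-degree
#' rotations and their compositions) per tile, identically to the image and
#' its mask. Rigid transforms permute pixels, so labels are preserved
#' exactly — no interpolation artefacts.
#'
#' @param images Array `N x h x w x c`.
#' @param masks Array `N x h x w x k` (same N, h, w).
#' @param seed Integer seed.
#' @return List with transformed `images`, `masks`, and the per-tile
#'   `transforms` applied.
#' @export
augment_batch <- function(images, masks, seed = 1L) {
  di <- dim(images); dm <- dim(masks)
  if (length(di) != 4 || length(dm) != 4 || di[1] != dm[1] ||
      any(di[2:3] != dm[2:3])) {
    stop("images and masks must be paired N x h x w x c arrays")
  }
  with_local_seed(seed, {
    tr <- sample(dihedral_transforms(), di[1], replace = TRUE)
  })
  for (k in seq_len(di[1])) {
    if (tr[k] == "identity") next
    images[k, , , ] <- dihedral_apply(array(images[k, , , ], di[2:4]), tr[k])
    masks[k, , , ] <- dihedral_apply(array(masks[k, , , ], dm[2:4]), tr[k])
  }
  list(images = images, masks = masks, transforms = tr)
}

# Subset a tile_set by split label.
tiles_subset <- function(tiles, split) {
  keep <- which(tiles$split %in% split)
  tiles$images <- tiles$images[keep, , , , drop = FALSE]
  tiles$masks <- tiles$masks[keep, , , , drop = FALSE]
  tiles$split <- tiles$split[keep]
  tiles$provenance <- tiles$provenance[keep, , drop = FALSE]
  tiles
}
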