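#' Segmentation architecture specification
#'
#' Describes one of the two encoder-decoder variants. The default (`"full"`
#' preset) specs are: UNET with encoder filters 16, 32, 64, 128 and a
#' 256-filter bottleneck; UNET-GRU with encoder filters 64, 128, 256, 512, a
#' 1024-filter bottleneck and a 512-unit gated recurrent layer applied over
#' the row-major flattened bottleneck feature map. Both take 256 x 256 x 3
#' (NIR, Red, Green) tiles, use 3x3 convolution pairs with ReLU, 2x2 max
#' pooling, 20% dropout after each convolution block, transposed-convolution
#' upsampling with skip concatenations, and a 1x1 convolution + per-pixel
#' SoftMax head over 2 classes. The `"desk"` preset is a reduced geometry
#' (2 blocks, filters from 8, 64 px tiles, 32 GRU units) for CPU-scale runs.
#'
#' @param variant `"unet"` or `"unet_gru"`.
#' @param preset `"full"` (default) or `"desk"`.
#' @param input_size Tile edge in pixels; must be divisible by
#'   `2^length(encoder_filters)`.
#' @param in_channels Input bands (default 3).
#' @param encoder_filters Ordered encoder filter counts (doubling).
#' @param bottleneck_filters Bottleneck filter count.
#' @param gru_units Recurrent units (unet_gru only).
#' @param dropout_rate Dropout fraction after each conv block (default 0.2).
#' @param decoder_dropout Mirror dropout in decoder blocks (default TRUE).
#' @param n_classes Output classes (default 2: unburnt, burnt).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(variant = c("unet", "unet_gru"),
                              preset = c("full", "desk"),
                              input_size = NULL, in_channels = 3L,
                              encoder_filters = NULL,
                              bottleneck_filters = NULL,
                              gru_units = NULL,
                              dropout_rate = 0.2,
                              decoder_dropout = TRUE,
                              n_classes = 2L) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  defaults <- if (preset == "full") {
    if (variant == "unet") {
      list(input_size = 256L, encoder_filters = c(16L, 32L, 64L, 128L),
           bottleneck_filters = 256L, gru_units = NULL)
    } else {
      list(input_size = 256L, encoder_filters = c(64L, 128L, 256L, 512L),
           bottleneck_filters = 1024L, gru_units = 512L)
    }
  } else {
    list(input_size = 64L, encoder_filters = c(8L, 16L),
         bottleneck_filters = 32L,
         gru_units = if (variant == "unet_gru") 32L else NULL)
  }
  input_size <- as.integer(input_size %||% defaults$input_size)
  encoder_filters <- as.integer(encoder_filters %||% defaults$encoder_filters)
  bottleneck_filters <- as.integer(bottleneck_filters %||% defaults$bottleneck_filters)
  if (variant == "unet_gru") {
    gru_units <- as.integer(gru_units %||% defaults$gru_units)
    stopifnot(gru_units > 0)
  } else {
    gru_units <- NULL
  }
  depth <- length(encoder_filters)
  if (input_size %% (2^depth) != 0) {
    stop(sprintf("input_size %d is not divisible by 2^%d", input_size, depth))
  }
  stopifnot(dropout_rate >= 0, dropout_rate < 1, n_classes >= 2)
  structure(
    list(variant = variant, preset = preset, input_size = input_size,
         in_channels = as.integer(in_channels),
         encoder_filters = encoder_filters,
         decoder_filters = rev(encoder_filters),
         bottleneck_filters = bottleneck_filters,
         gru_units = gru_units, dropout_rate = dropout_rate,
         decoder_dropout = decoder_dropout, n_classes = as.integer(n_classes)),
    class = "architecture_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s (%s): input %dx%dx%d, encoder [%s], bottleneck %d%s\n",
              x$variant, x$preset, x$input_size, x$input_size, x$in_channels,
              paste(x$encoder_filters, collapse = ", "), x$bottleneck_filters,
              if (!is.null(x$gru_units)) sprintf(", GRU %d units", x$gru_units) else ""))
  invisible(x)
}

# He (Kaiming) fan-in initialisation for one weight matrix.
he_weight <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

init_params <- function(spec, seed = 1L) {
  with_local_seed(seed, {
    p <- list()
    conv <- function(name, cin, cout) {
      p[[paste0(name, ".W")]] <<- he_weight(9 * cin, c(9 * cin, cout))
      p[[paste0(name, ".b")]] <<- rep(0, cout)
    }
    cin <- spec$in_channels
    for (k in seq_along(spec$encoder_filters)) {
      f <- spec$encoder_filters[k]
      conv(sprintf("enc%d.conv1", k), cin, f)
      conv(sprintf("enc%d.conv2", k), f, f)
      cin <- f
    }
    conv("bott.conv1", cin, spec$bottleneck_filters)
    conv("bott.conv2", spec$bottleneck_filters, spec$bottleneck_filters)
    top <- spec$bottleneck_filters
    if (!is.null(spec$gru_units)) {
      D <- spec$bottleneck_filters; U <- spec$gru_units
      for (gate in c("z", "r", "h")) {
        p[[paste0("gru.W", gate)]] <- he_weight(D, c(D, U))
        p[[paste0("gru.U", gate)]] <- he_weight(U, c(U, U))
        p[[paste0("gru.b", gate)]] <- rep(0, U)
      }
      top <- U
    }
    for (k in rev(seq_along(spec$encoder_filters))) {
      f <- spec$encoder_filters[k]
      p[[sprintf("up%d.W", k)]] <- he_weight(top, c(4 * top, f))
      p[[sprintf("up%d.b", k)]] <- rep(0, f)
      conv(sprintf("dec%d.conv1", k), 2 * f, f)
      conv(sprintf("dec%d.conv2", k), f, f)
      top <- f
    }
    p[["head.W"]] <- he_weight(top, c(top, spec$n_classes))
    p[["head.b"]] <- rep(0, spec$n_classes)
    p
  })
}

#' Build an untrained UNET segmentation model
#'
#' @param spec An [architecture_spec()] with `variant = "unet"`; default the
#'   full-size spec.
#' @param seed Seed for He weight initialisation.
#' @return A `segmentation_model` (list of `spec`, `params`).
#' @export
build_unet <- function(spec = architecture_spec("unet"), seed = 1L) {
  stopifnot(spec$variant == "unet")
  structure(list(spec = spec, params = init_params(spec, seed)),
            class = "segmentation_model")
}

#' Build an untrained UNET-GRU segmentation model
#'
#' As [build_unet()] but with the deeper encoder and a gated recurrent layer
#' at the bottleneck: the bottleneck feature map is flattened row-major into
#' a sequence (one step per spatial position), run through the GRU emitting
#' an output at every step, and reshaped back to spatial dimensions for the
#' decoder.
#'
#' @param spec An [architecture_spec()] with `variant = "unet_gru"`.
#' @param seed Seed for He weight initialisation.
#' @return A `segmentation_model`.
#' @export
build_unet_gru <- function(spec = architecture_spec("unet_gru"), seed = 1L) {
  stopifnot(spec$variant == "unet_gru")
  structure(list(spec = spec, params = init_params(spec, seed)),
            class = "segmentation_model")
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("<segmentation_model> %s, %s parameters%s\n", x$spec$variant,
              format(count_params(x), big.mark = ","),
              if (!is.null(x$history)) sprintf(", trained %d epochs", nrow(x$history)) else " (untrained)"))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `segmentation_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# spatial (S,S,C) -> row-major sequence (S*S, C): step t = (i-1)*S + j
flatten_rowmajor <- function(x) {
  d <- dim(x)
  t(matrix(aperm(x, c(3, 2, 1)), d[3], d[1] * d[2]))
}

unflatten_rowmajor <- function(X, S) {
  aperm(array(t(X), c(ncol(X), S, S)), c(3, 2, 1))
}

# Full forward pass for one tile. Returns logits, probs and (optionally) the
# caches needed by net_backward. Dropout draws from the current RNG stream.
net_forward <- function(params, x, spec, training = FALSE,
                        keep_cache = training) {
  depth <- length(spec$encoder_filters)
  cache <- list(enc = vector("list", depth), dec = vector("list", depth))
  skips <- vector("list", depth)
  h <- x
  for (k in seq_len(depth)) {
    c1 <- conv3_fwd(h, params[[sprintf("enc%d.conv1.W", k)]],
                    params[[sprintf("enc%d.conv1.b", k)]], keep_cache)
    r1 <- relu_fwd(c1$out, keep_cache)
    c2 <- conv3_fwd(r1$out, params[[sprintf("enc%d.conv2.W", k)]],
                    params[[sprintf("enc%d.conv2.b", k)]], keep_cache)
    r2 <- relu_fwd(c2$out, keep_cache)
    dr <- dropout_fwd(r2$out, spec$dropout_rate, training, keep_cache)
    skips[[k]] <- dr$out
    mp <- maxpool_fwd(dr$out, keep_cache)
    h <- mp$out
    if (keep_cache) {
      cache$enc[[k]] <- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                             r2 = r2$cache, dr = dr$cache, mp = mp$cache)
    }
  }
  b1 <- conv3_fwd(h, params[["bott.conv1.W"]], params[["bott.conv1.b"]], keep_cache)
  br1 <- relu_fwd(b1$out, keep_cache)
  b2 <- conv3_fwd(br1$out, params[["bott.conv2.W"]], params[["bott.conv2.b"]], keep_cache)
  br2 <- relu_fwd(b2$out, keep_cache)
  bd <- dropout_fwd(br2$out, spec$dropout_rate, training, keep_cache)
  h <- bd$out
  if (keep_cache) {
    cache$bott <- list(b1 = b1$cache, br1 = br1$cache, b2 = b2$cache,
                       br2 = br2$cache, bd = bd$cache)
  }
  if (!is.null(spec$gru_units)) {
    S <- dim(h)[1]
    X <- flatten_rowmajor(h)
    g <- gru_fwd(X, list(Wz = params[["gru.Wz"]], Uz = params[["gru.Uz"]],
                         bz = params[["gru.bz"]], Wr = params[["gru.Wr"]],
                         Ur = params[["gru.Ur"]], br = params[["gru.br"]],
                         Wh = params[["gru.Wh"]], Uh = params[["gru.Uh"]],
                         bh = params[["gru.bh"]]), keep_cache)
    h <- unflatten_rowmajor(g$out, S)
    if (keep_cache) cache$gru <- list(g = g$cache, S = S)
  }
  for (k in rev(seq_len(depth))) {
    up <- upconv_fwd(h, params[[sprintf("up%d.W", k)]],
                     params[[sprintf("up%d.b", k)]], keep_cache)
    cat_in <- array(c(up$out, skips[[k]]),
                    c(dim(up$out)[1], dim(up$out)[2],
                      dim(up$out)[3] + dim(skips[[k]])[3]))
    c1 <- conv3_fwd(cat_in, params[[sprintf("dec%d.conv1.W", k)]],
                    params[[sprintf("dec%d.conv1.b", k)]], keep_cache)
    r1 <- relu_fwd(c1$out, keep_cache)
    c2 <- conv3_fwd(r1$out, params[[sprintf("dec%d.conv2.W", k)]],
                    params[[sprintf("dec%d.conv2.b", k)]], keep_cache)
    r2 <- relu_fwd(c2$out, keep_cache)
    dr <- dropout_fwd(r2$out,
                      if (spec$decoder_dropout) spec$dropout_rate else 0,
                      training, keep_cache)
    h <- dr$out
    if (keep_cache) {
      cache$dec[[k]] <- list(up = up$cache, nup = dim(up$out)[3],
                             c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                             r2 = r2$cache, dr = dr$cache)
    }
  }
  hd <- conv1_fwd(h, params[["head.W"]], params[["head.b"]], keep_cache)
  if (keep_cache) cache$head <- hd$cache
  list(logits = hd$out, probs = softmax_hw(hd$out), cache = cache)
}

# Backward pass matching net_forward; returns gradients named like params.
net_backward <- function(params, cache, dlogits, spec) {
  depth <- length(spec$encoder_filters)
  g <- list()
  hb <- conv1_bwd(dlogits, cache$head, params[["head.W"]])
  g[["head.W"]] <- hb$dW; g[["head.b"]] <- hb$db
  d <- hb$dx
  dskips <- vector("list", depth)
  for (k in seq_len(depth)) {
    cc <- cache$dec[[k]]
    d1 <- dropout_bwd(d, cc$dr)
    d1 <- relu_bwd(d1, cc$r2)
    cb2 <- conv3_bwd(d1, cc$c2, params[[sprintf("dec%d.conv2.W", k)]])
    g[[sprintf("dec%d.conv2.W", k)]] <- cb2$dW
    g[[sprintf("dec%d.conv2.b", k)]] <- cb2$db
    d1 <- relu_bwd(cb2$dx, cc$r1)
    cb1 <- conv3_bwd(d1, cc$c1, params[[sprintf("dec%d.conv1.W", k)]])
    g[[sprintf("dec%d.conv1.W", k)]] <- cb1$dW
    g[[sprintf("dec%d.conv1.b", k)]] <- cb1$db
    nup <- cc$nup
    dcat <- cb1$dx
    dup <- dcat[, , seq_len(nup), drop = FALSE]
    dskips[[k]] <- dcat[, , nup + seq_len(dim(dcat)[3] - nup), drop = FALSE]
    ub <- upconv_bwd(dup, cc$up, params[[sprintf("up%d.W", k)]])
    g[[sprintf("up%d.W", k)]] <- ub$dW; g[[sprintf("up%d.b", k)]] <- ub$db
    d <- ub$dx
  }
  if (!is.null(spec$gru_units)) {
    S <- cache$gru$S
    dH <- flatten_rowmajor(d)
    gb <- gru_bwd(dH, cache$gru$g, list(
      Wz = params[["gru.Wz"]], Uz = params[["gru.Uz"]], bz = params[["gru.bz"]],
      Wr = params[["gru.Wr"]], Ur = params[["gru.Ur"]], br = params[["gru.br"]],
      Wh = params[["gru.Wh"]], Uh = params[["gru.Uh"]], bh = params[["gru.bh"]]))
    for (gate in c("z", "r", "h")) {
      g[[paste0("gru.W", gate)]] <- gb$grads[[paste0("W", gate)]]
      g[[paste0("gru.U", gate)]] <- gb$grads[[paste0("U", gate)]]
      g[[paste0("gru.b", gate)]] <- drop(gb$grads[[paste0("b", gate)]])
    }
    d <- unflatten_rowmajor(gb$dX, S)
  }
  cb <- cache$bott
  d1 <- dropout_bwd(d, cb$bd)
  d1 <- relu_bwd(d1, cb$br2)
  bb2 <- conv3_bwd(d1, cb$b2, params[["bott.conv2.W"]])
  g[["bott.conv2.W"]] <- bb2$dW; g[["bott.conv2.b"]] <- bb2$db
  d1 <- relu_bwd(bb2$dx, cb$br1)
  bb1 <- conv3_bwd(d1, cb$b1, params[["bott.conv1.W"]])
  g[["bott.conv1.W"]] <- bb1$dW; g[["bott.conv1.b"]] <- bb1$db
  d <- bb1$dx
  for (k in rev(seq_len(depth))) {
    ce <- cache$enc[[k]]
    dpool <- maxpool_bwd(d, ce$mp)
    dpool <- dpool + dskips[[k]]
    d1 <- dropout_bwd(dpool, ce$dr)
    d1 <- relu_bwd(d1, ce$r2)
    cb2 <- conv3_bwd(d1, ce$c2, params[[sprintf("enc%d.conv2.W", k)]])
    g[[sprintf("enc%d.conv2.W", k)]] <- cb2$dW
    g[[sprintf("enc%d.conv2.b", k)]] <- cb2$db
    d1 <- relu_bwd(cb2$dx, ce$r1)
    cb1 <- conv3_bwd(d1, ce$c1, params[[sprintf("enc%d.conv1.W", k)]],
                     need_dx = k > 1)
    g[[sprintf("enc%d.conv1.W", k)]] <- cb1$dW
    g[[sprintf("enc%d.conv1.b", k)]] <- cb1$db
    d <- cb1$dx
  }
  g
}

#' Forward pass on a single tile
#'
#' @param model A `segmentation_model`.
#' @param tile Array `t x t x in_channels`.
#' @return Array `t x t x n_classes` of per-pixel class probabilities
#'   (SoftMax-normalised).
#' @export
predict_probs <- function(model, tile) {
  stopifnot(inherits(model, "segmentation_model"))
  d <- dim(tile)
  if (d[1] != model$spec$input_size || d[2] != model$spec$input_size ||
      d[3] != model$spec$in_channels) {
    stop(sprintf("tile must be %d x %d x %d", model$spec$input_size,
                 model$spec$input_size, model$spec$in_channels))
  }
  net_forward(model$params, tile, model$spec, training = FALSE,
              keep_cache = FALSE)$probs
}

#' Predict a burnt/unburnt mask
#'
#' Per-pixel class is the argmax of the SoftMax probabilities, ties broken
#' toward class 0 (unburnt). For a `tile_set`, returns one predicted mask
#' per tile; for a full [reflectance_scene()], the scene is tiled internally
#' (stride = tile size, with edge tiles anchored to the scene border so the
#' whole grid is covered) and the per-tile predictions are mosaicked back
#' onto the scene grid.
#'
#' @param model A trained `segmentation_model`.
#' @param x A `tile_set` or a [reflectance_scene()].
#' @return For a scene: a [burn_mask()] on the scene grid. For a tile set:
#'   an integer array `N x t x t` of 0/1 predictions.
#' @export
predict_mask <- function(model, x) {
  stopifnot(inherits(model, "segmentation_model"))
  ts <- model$spec$input_size
  if (inherits(x, "tile_set")) {
    if (x$tile_size != ts) stop("tile size does not match model input size")
    if (dim(x$images)[4] != model$spec$in_channels) {
      stop("tile band count does not match model input channels")
    }
    n <- dim(x$images)[1]
    out <- array(0L, c(n, ts, ts))
    for (k in seq_len(n)) {
      p <- predict_probs(model, array(x$images[k, , , ], c(ts, ts, dim(x$images)[4])))
      out[k, , ] <- collapse_one_hot(p)
    }
    return(out)
  }
  if (inherits(x, "reflectance_scene")) {
    need <- c("NIR", "Red", "Green")
    if (!all(need %in% x$bands)) {
      stop("scene lacks the model's input bands: ",
           paste(setdiff(need, x$bands), collapse = ", "))
    }
    bidx <- match(need, x$bands)
    h <- x$grid$height; w <- x$grid$width
    if (h < ts || w < ts) stop("scene smaller than the model tile size")
    offs_r <- unique(c(seq(0, h - ts, by = ts), h - ts))
    offs_c <- unique(c(seq(0, w - ts, by = ts), w - ts))
    m <- matrix(0L, h, w)
    for (ro in offs_r) for (co in offs_c) {
      tile <- x$values[ro + seq_len(ts), co + seq_len(ts), bidx]
      p <- predict_probs(model, tile)
      m[ro + seq_len(ts), co + seq_len(ts)] <- collapse_one_hot(p)
    }
    return(burn_mask(m, x$grid))
  }
  stop("x must be a tile_set or reflectance_scene")
}
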