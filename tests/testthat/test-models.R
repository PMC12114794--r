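test_that("architecture specs encode the two published variants", {
  u <- architecture_spec("unet")
  expect_equal(u$encoder_filters, c(16L, 32L, 64L, 128L))
  expect_equal(u$bottleneck_filters, 256L)
  expect_null(u$gru_units)
  expect_equal(u$input_size, 256L)
  expect_equal(u$dropout_rate, 0.2)
  expect_equal(u$decoder_filters, c(128L, 64L, 32L, 16L))
  g <- architecture_spec("unet_gru")
  expect_equal(g$encoder_filters, c(64L, 128L, 256L, 512L))
  expect_equal(g$bottleneck_filters, 1024L)
  expect_equal(g$gru_units, 512L)
  expect_equal(g$decoder_filters, c(512L, 256L, 128L, 64L))
  # bottleneck spatial size: 256 / 2^4 = 16
  expect_equal(u$input_size / 2^length(u$encoder_filters), 16)
  expect_error(architecture_spec("unet", input_size = 100), "divisible")
})

test_that("forward passes produce per-pixel SoftMax probabilities of the right shape", {
  set.seed(5)
  for (variant in c("unet", "unet_gru")) {
    m <- if (variant == "unet") {
      build_unet(architecture_spec("unet", preset = "desk"), seed = 2)
    } else {
      build_unet_gru(architecture_spec("unet_gru", preset = "desk"), seed = 2)
    }
    p <- predict_probs(m, array(runif(64 * 64 * 3), c(64, 64, 3)))
    expect_equal(dim(p), c(64, 64, 2))
    expect_true(all(abs(p[, , 1] + p[, , 2] - 1) < 1e-6))
    expect_true(all(p >= 0))
  }
})

test_that("the bottleneck feature map has the downsampled spatial size", {
  spec <- architecture_spec("unet", preset = "desk", input_size = 32,
                            encoder_filters = c(2L, 3L, 4L, 5L),
                            bottleneck_filters = 6L)
  m <- build_unet(spec, seed = 3)
  fwd <- crossburn:::net_forward(m$params, array(runif(32 * 32 * 3), c(32, 32, 3)),
                                 spec, training = TRUE)
  expect_equal(fwd$cache$bott$b1$dims[1:2], c(2, 2)) # 32 / 2^4
})

test_that("the recurrent bottleneck sees a row-major sequence of every spatial position", {
  spec <- micro_arch("unet_gru") # 16 px input, 2 blocks -> 4x4 bottleneck
  m <- build_unet_gru(spec, seed = 4)
  fwd <- crossburn:::net_forward(m$params, array(runif(16 * 16 * 3), c(16, 16, 3)),
                                 spec, training = TRUE)
  expect_equal(nrow(fwd$cache$gru$g$X), 16) # (16/4)^2 steps
  expect_equal(ncol(fwd$cache$gru$g$H), spec$gru_units)
  # full-size spec: 256/2^4 = 16 -> 256-step sequence, 512 units
  g <- architecture_spec("unet_gru")
  expect_equal((g$input_size / 2^length(g$encoder_filters))^2, 256)
  expect_equal(g$gru_units, 512L)
  # row-major flattening round-trips
  x <- array(runif(4 * 4 * 3), c(4, 4, 3))
  X <- crossburn:::flatten_rowmajor(x)
  expect_equal(X[2, ], x[1, 2, ]) # step 2 is row 1, column 2
  expect_equal(crossburn:::unflatten_rowmajor(X, 4), x)
})

test_that("UNET-GRU has strictly more trainable parameters than UNET", {
  u <- build_unet(architecture_spec("unet"), seed = 1)
  g <- build_unet_gru(architecture_spec("unet_gru"), seed = 1)
  expect_gt(count_params(g), count_params(u))
})

test_that("weight initialisation is reproducible given a seed", {
  a <- build_unet(architecture_spec("unet", preset = "desk"), seed = 9)
  b <- build_unet(architecture_spec("unet", preset = "desk"), seed = 9)
  expect_identical(a$params, b$params)
  c <- build_unet(architecture_spec("unet", preset = "desk"), seed = 10)
  expect_false(identical(a$params, c$params))
})

test_that("analytic gradients match finite differences for both variants", {
  set.seed(42)
  for (variant in c("unet", "unet_gru")) {
    spec <- architecture_spec(variant, preset = "desk", input_size = 8,
                              encoder_filters = c(3L, 4L),
                              bottleneck_filters = 5L,
                              gru_units = if (variant == "unet_gru") 4L else NULL,
                              dropout_rate = 0)
    params <- crossburn:::init_params(spec, seed = 7)
    x <- array(runif(8 * 8 * 3), c(8, 8, 3))
    t <- one_hot_mask(matrix(rbinom(64, 1, 0.4), 8, 8))
    fwd <- crossburn:::net_forward(params, x, spec, training = TRUE)
    sc <- crossburn:::softmax_ce(fwd$logits, t)
    g <- crossburn:::net_backward(params, fwd$cache, sc$dlogits, spec)
    loss_at <- function(p) {
      f <- crossburn:::net_forward(p, x, spec, training = FALSE, keep_cache = FALSE)
      crossburn:::softmax_ce(f$logits, t)$loss
    }
    eps <- 1e-6
    for (nm in sample(names(params), 8)) {
      i <- sample(length(params[[nm]]), 1)
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-8, abs(num) + abs(g[[nm]][i])),
                1e-4)
    }
  }
})

test_that("argmax prediction breaks ties toward the unburnt class", {
  oh <- array(0, c(1, 2, 2))
  oh[1, 1, ] <- c(0.9, 0.1)
  oh[1, 2, ] <- c(0.5, 0.5)
  expect_equal(collapse_one_hot(oh), matrix(c(0L, 0L), 1, 2))
  oh[1, 2, ] <- c(0.4, 0.6)
  expect_equal(collapse_one_hot(oh), matrix(c(0L, 1L), 1, 2))
})

test_that("scene prediction equals the mosaic of per-tile predictions", {
  set.seed(10)
  m <- build_unet(micro_arch("unet"), seed = 6)
  h <- 32 # 2x2 tiles of 16
  sc <- reflectance_scene(array(runif(h * h * 4), c(h, h, 4)),
                          grid_spec(h, h, 30), c("Blue", "Green", "Red", "NIR"))
  full <- predict_mask(m, sc)
  bidx <- match(c("NIR", "Red", "Green"), sc$bands)
  for (ro in c(0L, 16L)) for (co in c(0L, 16L)) {
    tile <- sc$values[ro + 1:16, co + 1:16, bidx]
    p <- collapse_one_hot(predict_probs(m, tile))
    expect_equal(full$mask[ro + 1:16, co + 1:16], p)
  }
  expect_error(predict_mask(m, constant_scene(32, 32, 0.3, bands = c("B1", "B2"))),
               "bands")
})
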