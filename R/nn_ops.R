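# Low-level neural-network primitives.
#
# Activations are H x W x C arrays for a single tile; convolutions are
# evaluated as im2col matrix products so the heavy lifting is one BLAS
# GEMM per layer. Every forward returns the cache its backward needs.

# --- 3x3 same-padding convolution -----------------------------------------

# Patch-gather index maps are pure functions of the activation shape, so
# they are built once per (H, W, C) and cached for the whole session.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, C) {
  key <- paste(H, W, C, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  # linear index into the zero-padded (Hp, Wp, C) array for interior cells
  interior <- as.vector(outer(
    outer(2:(H + 1L), (2:(W + 1L) - 1L) * Hp, "+"),
    (seq_len(C) - 1L) * Hp * Wp, "+"
  ))
  # gather: (H*W) x (9*C) matrix of padded linear indices; column blocks
  # ordered by kernel offset (dj-major, di within) then input channel
  base <- outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+") # (1-based, offset 0)
  gather <- integer(H * W * 9L * C)
  pos <- 0L
  n <- H * W
  for (dj in 0:2) for (di in 0:2) {
    off <- di + dj * Hp
    blk <- as.vector(base) + off
    for (c in seq_len(C)) {
      gather[pos + seq_len(n)] <- blk + (c - 1L) * Hp * Wp
      pos <- pos + n
    }
  }
  out <- list(interior = interior, gather = gather,
              npad = Hp * Wp * C, n = n)
  .conv_idx_cache[[key]] <- out
  out
}

# (H*W) x (9*C) patch matrix via one cached gather.
im2col3 <- function(x) {
  d <- dim(x)
  ix <- conv_indices(d[1], d[2], d[3])
  xp <- numeric(ix$npad)
  xp[ix$interior] <- x
  out <- xp[ix$gather]
  dim(out) <- c(ix$n, 9L * d[3])
  out
}

# Permutation turning the forward weight (9*Cin x Cout) into the transposed
# kernel (9*Cout x Cin) with spatially flipped offsets, so the data gradient
# is itself a same-padding convolution of dout (gather + GEMM, no scatter).
.flip_idx_cache <- new.env(parent = emptyenv())

flip_perm <- function(Cin, Cout) {
  key <- paste(Cin, Cout, sep = "_")
  hit <- .flip_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 0:8
  flip <- (2 - k %% 3) + 3 * (2 - k %/% 3)
  perm <- integer(9L * Cout * Cin)
  pos <- 0L
  for (ci in seq_len(Cin)) {
    for (kp in k) {
      src <- flip[kp + 1L] * Cin + ci # row in W for flipped offset, channel ci
      perm[pos + seq_len(Cout)] <- src + 9L * Cin * (seq_len(Cout) - 1L)
      pos <- pos + Cout
    }
  }
  .flip_idx_cache[[key]] <- perm
  perm
}

conv3_fwd <- function(x, W, b, keep_cache = TRUE) {
  d <- dim(x)
  xcol <- im2col3(x)
  y <- xcol %*% W
  y <- y + rep(b, each = nrow(y))
  list(out = array(y, c(d[1], d[2], ncol(W))),
       cache = if (keep_cache) list(xcol = xcol, dims = d) else NULL)
}

conv3_bwd <- function(dout, cache, W, need_dx = TRUE) {
  d <- cache$dims
  Cout <- dim(dout)[3]
  dmat <- matrix(dout, d[1] * d[2], Cout)
  dW <- crossprod(cache$xcol, dmat)
  db <- colSums(dmat)
  dx <- NULL
  if (need_dx) {
    Wback <- W[flip_perm(d[3], Cout)]
    dim(Wback) <- c(9L * Cout, d[3])
    dx <- im2col3(dout) %*% Wback
    dim(dx) <- d
  }
  list(dx = dx, dW = dW, db = db)
}

# --- 1x1 convolution (classification head) --------------------------------

conv1_fwd <- function(x, W, b, keep_cache = TRUE) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  y <- xm %*% W
  y <- y + rep(b, each = nrow(y))
  list(out = array(y, c(d[1], d[2], ncol(W))),
       cache = if (keep_cache) list(xm = xm, dims = d) else NULL)
}

conv1_bwd <- function(dout, cache, W) {
  d <- cache$dims
  dmat <- matrix(dout, d[1] * d[2], dim(dout)[3])
  list(dx = array(tcrossprod(dmat, W), d),
       dW = crossprod(cache$xm, dmat), db = colSums(dmat))
}

# --- pointwise layers ------------------------------------------------------

relu_fwd <- function(x, keep_cache = TRUE) {
  out <- x * (x > 0)
  list(out = out, cache = if (keep_cache) (x > 0) else NULL)
}

relu_bwd <- function(dout, mask) dout * mask

# Inverted dropout: scaling at train time keeps eval a pure identity.
dropout_fwd <- function(x, rate, training, keep_cache = TRUE) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = if (keep_cache) NULL else NULL))
  }
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, cache = if (keep_cache) mask else NULL)
}

dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# --- 2x2 max pooling, stride 2 --------------------------------------------

maxpool_fwd <- function(x, keep_cache = TRUE) {
  d <- dim(x)
  ri <- seq(1, d[1], by = 2); ci <- seq(1, d[2], by = 2)
  s <- list(
    x[ri, ci, , drop = FALSE], x[ri + 1, ci, , drop = FALSE],
    x[ri, ci + 1, , drop = FALSE], x[ri + 1, ci + 1, , drop = FALSE]
  )
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  amax <- NULL
  if (keep_cache) {
    amax <- array(1L, dim(out))
    best <- s[[1]]
    for (k in 2:4) {
      better <- s[[k]] > best
      amax[better] <- k
      best[better] <- s[[k]][better]
    }
  }
  list(out = out, cache = if (keep_cache) list(amax = amax, dims = d) else NULL)
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  ri <- seq(1, d[1], by = 2); ci <- seq(1, d[2], by = 2)
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (k in 1:4) {
    sel <- cache$amax == k
    if (!any(sel)) next
    block <- array(0, dim(dout))
    block[sel] <- dout[sel]
    dx[ri + offs[[k]][1], ci + offs[[k]][2], ] <-
      dx[ri + offs[[k]][1], ci + offs[[k]][2], , drop = FALSE] + block
  }
  dx
}

# --- 2x2 stride-2 transposed convolution (upsampling) ---------------------
# Kernel positions write disjoint 2x2 output blocks, so forward is four
# independent matrix products. Weight layout: (4*Cin) x Cout, position-major.

upconv_fwd <- function(x, W, b, keep_cache = TRUE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  Cout <- ncol(W)
  xm <- matrix(x, H * Wd, Cin)
  out <- array(0, c(2 * H, 2 * Wd, Cout))
  pos <- 0L
  for (b2 in 0:1) for (a in 0:1) {
    y <- xm %*% W[pos * Cin + seq_len(Cin), , drop = FALSE]
    out[seq(1 + a, 2 * H, 2), seq(1 + b2, 2 * Wd, 2), ] <- array(y, c(H, Wd, Cout))
    pos <- pos + 1L
  }
  out <- out + rep(b, each = 4 * H * Wd)
  list(out = out, cache = if (keep_cache) list(xm = xm, dims = d) else NULL)
}

upconv_bwd <- function(dout, cache, W) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; Cin <- d[3]
  Cout <- dim(dout)[3]
  dW <- matrix(0, nrow(W), ncol(W))
  dxm <- matrix(0, H * Wd, Cin)
  pos <- 0L
  for (b2 in 0:1) for (a in 0:1) {
    dy <- matrix(dout[seq(1 + a, 2 * H, 2), seq(1 + b2, 2 * Wd, 2), , drop = FALSE],
                 H * Wd, Cout)
    dW[pos * Cin + seq_len(Cin), ] <- crossprod(cache$xm, dy)
    dxm <- dxm + tcrossprod(dy, W[pos * Cin + seq_len(Cin), , drop = FALSE])
    pos <- pos + 1L
  }
  db <- colSums(matrix(dout, 4 * H * Wd, Cout))
  list(dx = array(dxm, d), dW = dW, db = db)
}

# --- gated recurrent unit over a feature sequence -------------------------
# Cho-style GRU: z and r gates, candidate with reset-scaled state,
# h_t = (1 - z) * h_prev + z * candidate; an output at every step.

gru_fwd <- function(X, p, keep_cache = TRUE) {
  T <- nrow(X); U <- ncol(p$Uz)
  # precompute input projections for all steps in three GEMMs
  XZ <- X %*% p$Wz; XR <- X %*% p$Wr; XH <- X %*% p$Wh
  H <- matrix(0, T, U)
  Z <- R <- Cc <- if (keep_cache) matrix(0, T, U) else NULL
  h <- rep(0, U)
  for (t in seq_len(T)) {
    z <- 1 / (1 + exp(-(XZ[t, ] + h %*% p$Uz + p$bz)))
    r <- 1 / (1 + exp(-(XR[t, ] + h %*% p$Ur + p$br)))
    cc <- tanh(XH[t, ] + (r * h) %*% p$Uh + p$bh)
    h <- (1 - z) * h + z * cc
    H[t, ] <- h
    if (keep_cache) { Z[t, ] <- z; R[t, ] <- r; Cc[t, ] <- cc }
  }
  list(out = H,
       cache = if (keep_cache) list(X = X, H = H, Z = Z, R = R, C = Cc) else NULL)
}

gru_bwd <- function(dH, cache, p) {
  X <- cache$X; H <- cache$H; Z <- cache$Z; R <- cache$R; Cc <- cache$C
  T <- nrow(X); U <- ncol(H)
  g <- list(Wz = 0 * p$Wz, Uz = 0 * p$Uz, bz = 0 * p$bz,
            Wr = 0 * p$Wr, Ur = 0 * p$Ur, br = 0 * p$br,
            Wh = 0 * p$Wh, Uh = 0 * p$Uh, bh = 0 * p$bh)
  dX <- matrix(0, T, ncol(X))
  dh_next <- rep(0, U)
  for (t in rev(seq_len(T))) {
    h_prev <- if (t > 1) H[t - 1, ] else rep(0, U)
    z <- Z[t, ]; r <- R[t, ]; cc <- Cc[t, ]
    dh <- dH[t, ] + dh_next
    dz <- dh * (cc - h_prev)
    dcc <- dh * z
    dh_prev <- dh * (1 - z)
    dcc_pre <- dcc * (1 - cc^2)
    drh <- drop(dcc_pre %*% t(p$Uh))
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    g$Wz <- g$Wz + tcrossprod(X[t, ], dz_pre)
    g$Wr <- g$Wr + tcrossprod(X[t, ], dr_pre)
    g$Wh <- g$Wh + tcrossprod(X[t, ], dcc_pre)
    g$Uz <- g$Uz + tcrossprod(h_prev, dz_pre)
    g$Ur <- g$Ur + tcrossprod(h_prev, dr_pre)
    g$Uh <- g$Uh + tcrossprod(r * h_prev, dcc_pre)
    g$bz <- g$bz + dz_pre
    g$br <- g$br + dr_pre
    g$bh <- g$bh + dcc_pre
    dX[t, ] <- dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr) + dcc_pre %*% t(p$Wh)
    dh_next <- dh_prev + drop(dz_pre %*% t(p$Uz)) + drop(dr_pre %*% t(p$Ur))
  }
  list(dX = dX, grads = g)
}

# --- softmax + categorical cross-entropy ----------------------------------

softmax_hw <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1] * d[2], d[3])
  mx <- m[, 1]
  for (j in 2:ncol(m)) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  array(e / rowSums(e), d)
}

# Mean per-pixel cross-entropy and its gradient w.r.t. the logits.
softmax_ce <- function(logits, target) {
  d <- dim(logits)
  probs <- softmax_hw(logits)
  n <- d[1] * d[2]
  eps <- 1e-12
  loss <- -sum(target * log(probs + eps)) / n
  dlogits <- (probs - target) / n
  list(loss = loss, probs = probs, dlogits = dlogits)
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
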