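#' Training configuration
#'
#' @param learning_rate Initial Adam learning rate (default 1e-4).
#' @param batch_size Tiles per gradient step (default 8).
#' @param epochs Training epochs (default 100 for the full-size preset; the
#'   reduced desk preset conventionally uses ~20).
#' @param plateau_factor Learning-rate multiplier applied after a plateau
#'   (default 0.5; must be in (0, 1)).
#' @param plateau_patience Epochs without validation-loss improvement before
#'   the rate is reduced (default 5).
#' @param min_learning_rate Learning-rate floor (default 1e-6).
#' @param augment_train Apply dihedral augmentation to training batches
#'   (default TRUE).
#' @param augment_validation Also augment validation batches — an unusual
#'   choice, off by default but available to mirror validation-generator
#'   pipelines.
#' @param seed Integer seed covering shuffling, augmentation and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 8L,
                            epochs = 100L, plateau_factor = 0.5,
                            plateau_patience = 5L, min_learning_rate = 1e-6,
                            augment_train = TRUE, augment_validation = FALSE,
                            seed = 1L) {
  stopifnot(learning_rate > 0, plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1, batch_size >= 1, epochs >= 1,
            min_learning_rate > 0)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), plateau_factor = plateau_factor,
         plateau_patience = as.integer(plateau_patience),
         min_learning_rate = min_learning_rate,
         augment_train = augment_train,
         augment_validation = augment_validation, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Best epoch under the checkpoint rule
#'
#' The retained model is the one from the epoch with minimum validation
#' loss (first such epoch on ties).
#'
#' @param val_loss Numeric vector of per-epoch validation losses.
#' @return Integer epoch index.
#' @export
select_best_epoch <- function(val_loss) {
  stopifnot(length(val_loss) >= 1)
  which.min(val_loss)
}

#' Learning-rate plateau schedule
#'
#' Replays the reduce-on-plateau rule over a validation-loss history: when
#' the loss has not improved on its best value for `patience` consecutive
#' epochs, the rate is multiplied by `factor` (never below `min_lr`) and the
#' wait counter resets. Returns the rate in force at each epoch.
#'
#' @param val_loss Numeric vector of per-epoch validation losses.
#' @param initial_lr Starting learning rate.
#' @param factor Multiplier in (0, 1).
#' @param patience Epochs without improvement before a reduction.
#' @param min_lr Floor on the learning rate.
#' @return Numeric vector: learning rate used during each epoch.
#' @export
plateau_schedule <- function(val_loss, initial_lr, factor = 0.5,
                             patience = 5L, min_lr = 1e-6) {
  lr <- initial_lr
  best <- Inf
  wait <- 0L
  out <- numeric(length(val_loss))
  for (e in seq_along(val_loss)) {
    out[e] <- lr
    if (val_loss[e] < best) {
      best <- val_loss[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- max(lr * factor, min_lr)
        wait <- 0L
      }
    }
  }
  out
}

eval_tiles <- function(params, spec, images, masks) {
  n <- dim(images)[1]
  loss <- 0
  correct <- 0
  ts <- dim(images)[2]
  for (k in seq_len(n)) {
    x <- array(images[k, , , ], dim(images)[2:4])
    t <- array(masks[k, , , ], dim(masks)[2:4])
    fwd <- net_forward(params, x, spec, training = FALSE, keep_cache = FALSE)
    sc <- softmax_ce(fwd$logits, t)
    loss <- loss + sc$loss
    pred <- collapse_one_hot(sc$probs)
    correct <- correct + sum(pred == t[, , 2])
  }
  list(loss = loss / n, accuracy = correct / (n * ts * ts))
}

#' Train a segmentation model
#'
#' Minimises per-pixel categorical cross-entropy with Adam at an initial
#' rate of 1e-4 (configurable), reducing the rate on validation-loss
#' plateaus and checkpointing the epoch with minimum validation loss; the
#' returned weights are the checkpointed ones. The run is fully seeded
#' (shuffling, augmentation, dropout), so identical configs reproduce
#' identical weights.
#'
#' @param model An untrained (or warm) `segmentation_model`.
#' @param tiles A `tile_set` with non-empty `train` and `validation` splits.
#' @param config A [training_config()].
#' @param verbose Print one line per epoch.
#' @return A `segmentation_model` with elements `history` (tibble: epoch,
#'   loss, accuracy, val_loss, val_accuracy, lr) and `best_epoch`, carrying
#'   the best-epoch weights in `params` (final-epoch weights in
#'   `final_params`).
#' @export
train <- function(model, tiles, config = training_config(), verbose = FALSE) {
  stopifnot(inherits(model, "segmentation_model"), inherits(tiles, "tile_set"),
            inherits(config, "training_config"))
  tr_idx <- which(tiles$split == "train")
  va_idx <- which(tiles$split == "validation")
  if (length(tr_idx) == 0) stop("tile set has an empty train split")
  if (length(va_idx) == 0) stop("tile set has an empty validation split")
  if (tiles$tile_size != model$spec$input_size) {
    stop("tile size does not match the model input size")
  }
  params <- model$params
  spec <- model$spec
  state <- adam_init(params)
  lr <- config$learning_rate
  best_loss <- Inf
  best_params <- params
  wait <- 0L
  hist <- vector("list", config$epochs)
  va_img <- tiles$images[va_idx, , , , drop = FALSE]
  va_msk <- tiles$masks[va_idx, , , , drop = FALSE]
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_img <- tiles$images[ord, , , , drop = FALSE]
      ep_msk <- tiles$masks[ord, , , , drop = FALSE]
      if (config$augment_train) {
        aug <- augment_batch(ep_img, ep_msk,
                             seed = config$seed + 7919L * epoch)
        ep_img <- aug$images; ep_msk <- aug$masks
      }
      n <- dim(ep_img)[1]
      tr_loss <- 0; tr_correct <- 0
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        idx <- s:min(s + config$batch_size - 1, n)
        grads <- NULL
        batch_loss <- 0
        for (k in idx) {
          x <- array(ep_img[k, , , ], dim(ep_img)[2:4])
          t <- array(ep_msk[k, , , ], dim(ep_msk)[2:4])
          fwd <- net_forward(params, x, spec, training = TRUE)
          sc <- softmax_ce(fwd$logits, t)
          if (!is.finite(sc$loss)) {
            stop(sprintf("non-finite loss at epoch %d (tile %d): aborting",
                         epoch, k))
          }
          batch_loss <- batch_loss + sc$loss
          tr_correct <- tr_correct + sum(collapse_one_hot(sc$probs) == t[, , 2])
          g <- net_backward(params, fwd$cache, sc$dlogits, spec)
          if (is.null(grads)) grads <- g
          else for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
        nb <- length(idx)
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / nb
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
        tr_loss <- tr_loss + batch_loss
      }
      tr_loss <- tr_loss / n
      tr_acc <- tr_correct / (n * tiles$tile_size^2)
      va_img_e <- va_img; va_msk_e <- va_msk
      if (config$augment_validation) {
        aug <- augment_batch(va_img_e, va_msk_e,
                             seed = config$seed + 104729L * epoch)
        va_img_e <- aug$images; va_msk_e <- aug$masks
      }
      ev <- eval_tiles(params, spec, va_img_e, va_msk_e)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = tr_loss, accuracy = tr_acc,
        val_loss = ev$loss, val_accuracy = ev$accuracy, lr = lr
      )
      if (verbose) {
        message(sprintf(
          "epoch %3d  loss %.4f acc %.4f  val_loss %.4f val_acc %.4f  lr %.2g",
          epoch, tr_loss, tr_acc, ev$loss, ev$accuracy, lr))
      }
      if (ev$loss < best_loss) {
        best_loss <- ev$loss
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$plateau_patience) {
          lr <- max(lr * config$plateau_factor, config$min_learning_rate)
          wait <- 0L
        }
      }
    }
  })
  history <- dplyr::bind_rows(hist)
  model$params <- best_params
  model$final_params <- params
  model$history <- history
  model$best_epoch <- select_best_epoch(history$val_loss)
  model$training_config <- config
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a segmentation model
#'
#' @param x A trained `segmentation_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `accuracy`,
#'   `val_loss`, `val_accuracy`, `lr`.
#' @export
tidy.segmentation_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has not been trained")
  x$history
}

#' One-row summary of a segmentation model
#'
#' @param x A `segmentation_model`.
#' @param ... Unused.
#' @return Tibble with `variant`, `n_params`, `epochs`, `best_epoch`,
#'   `best_val_loss`, `best_val_accuracy`.
#' @export
glance.segmentation_model <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant,
    n_params = count_params(x),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = if (is.null(x$history)) NA_real_ else x$history$val_loss[x$best_epoch],
    best_val_accuracy = if (is.null(x$history)) NA_real_ else x$history$val_accuracy[x$best_epoch]
  )
}
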