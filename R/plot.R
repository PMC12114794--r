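#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_tibble <- function(mat, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(mat)), times = ncol(mat)),
    col = rep(seq_len(ncol(mat)), each = nrow(mat)),
    !!value_name := as.vector(mat)
  )
}

#' Plot a reflectance scene band
#'
#' @param object A [reflectance_scene()].
#' @param band Band name to display (default NIR if present, else first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reflectance_scene <- function(object, band = NULL, ...) {
  band <- band %||% (if ("NIR" %in% object$bands) "NIR" else object$bands[1])
  b <- match(band, object$bands)
  if (is.na(b)) stop("band not present in scene: ", band)
  df <- raster_tibble(object$values[, , b], "reflectance")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$reflectance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(band, " reflectance"), x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a burnt-area mask
#'
#' @param object A [burn_mask()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.burn_mask <- function(object, ...) {
  df <- raster_tibble(object$mask, "burnt")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = factor(.data$burnt))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey20", `1` = "red"),
                               name = NULL,
                               labels = c(`0` = "unburnt", `1` = "burnt")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a land-cover map
#'
#' @param object A [land_cover_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.land_cover_map <- function(object, ...) {
  lab <- stats::setNames(names(object$legend), object$legend)
  df <- raster_tibble(object$classes, "code")
  df$class <- factor(lab[as.character(df$code)], levels = names(object$legend))
  pal <- c(forest = "#1b7837", water = "#2166ac", road_urban = "#878787",
           barren = "#d8b365", burnt = "#67000d")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, name = NULL, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot training curves
#'
#' @param object A trained `segmentation_model`.
#' @param ... Unused.
#' @return A ggplot of training/validation loss by epoch, with the
#'   checkpointed best epoch marked.
#' @export
autoplot.segmentation_model <- function(object, ...) {
  if (is.null(object$history)) stop("model has not been trained")
  df <- tidyr::pivot_longer(object$history[c("epoch", "loss", "val_loss")],
                            -"epoch", names_to = "series",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Comparative metric plot across experimental cases
#'
#' @param records List of `run_record`s (as from [run_all_cases()]).
#' @return A ggplot: one bar per metric per case.
#' @export
plot_case_metrics <- function(records) {
  tab <- dplyr::bind_rows(lapply(records, tidy))
  long <- tidyr::pivot_longer(
    tab[c("case", "precision", "recall", "f1", "accuracy", "iou", "dice")],
    -"case", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value,
                                     fill = .data$case)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "case") +
    ggplot2::theme_minimal()
}
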