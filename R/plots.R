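tissue_palette <- function() {
  c(VESSEL = "#b2182b", MUSCLE = "#ef8a62", TUMOUR = "#762a83",
    BENIGN = "#af8dc3", ADIPOSE = "#f7f7f7", LYMPHOCYTE = "#2166ac",
    LEUKOCYTE = "#8c510a", NERVE = "#dfc27d", STROMA = "#fddbc7",
    BACKGROUND = "#ffffff")
}

#' Plot a label map
#'
#' @param lm A [label_map()].
#' @param ... Unused.
#' @return A ggplot raster of the class map with the tissue palette.
#' @export
plot_label_map <- function(lm, ...) {
  stopifnot(inherits(lm, "label_map"))
  nm <- tissue_classes()$name
  df <- tidyr::expand_grid(row = seq_len(nrow(lm$labels)),
                           col = seq_len(ncol(lm$labels)))
  df$class <- factor(nm[as.vector(t(lm$labels))], levels = nm)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = tissue_palette(), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "tissue") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.label_map <- function(object, ...) plot_label_map(object, ...)

#' Plot the training loss history
#'
#' @param object An `angio_unet`.
#' @param ... Unused.
#' @return A ggplot of loss against epoch.
#' @export
autoplot.angio_unet <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "weighted soft Dice loss") +
    ggplot2::theme_minimal()
}

#' Plot a profile over distance rings
#'
#' @param profile Tibble from [lymphocytes_by_distance()] or
#'   [vessels_by_distance()].
#' @param y Bare name of the column to plot (e.g. `lymphocyte_pct`,
#'   `density_per_mm2`).
#' @return A ggplot of the ring profile against distance.
#' @export
plot_ring_profile <- function(profile, y) {
  yq <- rlang::ensym(y)
  ggplot2::ggplot(profile,
                  ggplot2::aes((.data$distance_lo_um + .data$distance_hi_um) / 2,
                               !!yq)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance (µm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
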