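#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a network
#'
#' @param x An `angio_unet`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `lr`, `loss`.
#' @export
tidy.angio_unet <- function(x, ...) x$history

#' One-row summary of a network
#'
#' @param x An `angio_unet`.
#' @param ... Unused.
#' @return Tibble: `depth`, `base_channels`, `n_classes`, `n_parameters`,
#'   `epochs_trained`, `final_loss`.
#' @export
glance.angio_unet <- function(x, ...) {
  npar <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b) +
                       length(l$gamma) + length(l$beta), numeric(1)))
  tibble::tibble(depth = x$config$depth,
                 base_channels = x$config$base_channels,
                 n_classes = x$config$n_classes,
                 n_parameters = npar,
                 epochs_trained = nrow(x$history),
                 final_loss = if (nrow(x$history)) {
                   x$history$loss[nrow(x$history)]
                 } else NA_real_)
}

#' Tidy a detection report
#'
#' @param x A `detection_report` from [detect_vessels()].
#' @param ... Unused.
#' @return The report in long form: `metric`, `value`.
#' @export
tidy.detection_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value",
                        values_transform = as.numeric)
}
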