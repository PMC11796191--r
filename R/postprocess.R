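#' Post-processing configuration
#'
#' Parameters of the five-rule cleanup cascade applied after inference:
#' Gaussian smoothing of all probability planes except vessels and
#' leukocytes, then size-thresholded hole filling for background (< 10000
#' px), stroma (< 1000 px, protecting vessels and leukocytes), adipose
#' (< 10000 px, same protection) and vessels (no size limit, overwriting
#' any class — this restores hollow lumens to filled vessels). Thresholds
#' are strict ("smaller than").
#'
#' @param sigma Smoothing sigma in pixels.
#' @param background_hole_px,stroma_hole_px,adipose_hole_px Hole-size
#'   thresholds (pixels, strict less-than).
#' @param protected Classes never overwritten by the stroma/adipose rules.
#' @return List of class `postprocess_config`.
#' @export
postprocess_config <- function(sigma = 2, background_hole_px = 10000,
                               stroma_hole_px = 1000,
                               adipose_hole_px = 10000,
                               protected = c("VESSEL", "LEUKOCYTE")) {
  stopifnot(background_hole_px > 0, stroma_hole_px > 0, adipose_hole_px > 0)
  structure(list(sigma = sigma, background_hole_px = background_hole_px,
                 stroma_hole_px = stroma_hole_px,
                 adipose_hole_px = adipose_hole_px,
                 protected = protected),
            class = "postprocess_config")
}

#' Smooth probability planes, exempting vessels and leukocytes
#'
#' Convolves every class plane except the exempt ones with an isotropic
#' Gaussian, then renormalizes per pixel. The fine vessel and leukocyte
#' structures are exempt to retain their level of detail.
#'
#' @param stack Probability array `[H, W, C]`.
#' @param sigma Gaussian sigma (pixels); 0 is the identity.
#' @param exempt Class names excluded from smoothing.
#' @return Smoothed, renormalized stack.
#' @export
smooth_probabilities <- function(stack, sigma = 2,
                                 exempt = c("VESSEL", "LEUKOCYTE")) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(stack)
  d <- dim(stack)
  keep <- class_code(exempt)
  for (j in seq_len(d[3])) {
    if (j %in% keep) next
    stack[, , j] <- as.matrix(EBImage::gblur(stack[, , j], sigma,
                                             boundary = "replicate"))
  }
  tot <- rowSums(matrix(stack, d[1] * d[2], d[3]))
  for (j in seq_len(d[3])) stack[, , j] <- stack[, , j] / tot
  stack
}

# fill enclosed holes of class `code`: connected components (4-connectivity,
# the dual of the 8-connected foreground) of non-`code` pixels that do not
# touch the image border and are smaller than `max_px`
fill_holes_class <- function(labels, code, max_px, protect = integer(0)) {
  mask <- labels == code
  if (!any(mask)) return(labels)
  comp <- cpp_label_components(!mask, 4L)
  border_ids <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  border_ids <- border_ids[border_ids > 0]
  n <- max(comp)
  if (n == 0) return(labels)
  sizes <- tabulate(comp, n)
  fill_ids <- setdiff(which(sizes < max_px), border_ids)
  if (!length(fill_ids)) return(labels)
  sel <- matrix(comp %in% fill_ids, nrow(labels))
  if (length(protect)) sel <- sel & !(labels %in% protect)
  labels[sel] <- code
  labels
}

#' Apply the class-aware hole-filling cascade
#'
#' Runs the four hole-filling rules in order on a voted label map:
#' background holes < 10000 px become background; stroma holes < 1000 px
#' become stroma (never overwriting vessels or leukocytes); adipose holes
#' < 10000 px become adipose (same protection); vessel holes of any size
#' become vessel, overwriting anything. A "hole" of a class is a
#' 4-connected component of other-class pixels fully enclosed by that class
#' (not touching the image border). Note the background rule, first in the
#' cascade, carries no protection.
#'
#' @param lm A [label_map()] from [vote()].
#' @param config A [postprocess_config()].
#' @return The cleaned [label_map()].
#' @export
apply_cascade <- function(lm, config = postprocess_config()) {
  stopifnot(inherits(lm, "label_map"))
  labels <- lm$labels
  protect <- class_code(config$protected)
  labels <- fill_holes_class(labels, class_code("BACKGROUND"),
                             config$background_hole_px)
  labels <- fill_holes_class(labels, class_code("STROMA"),
                             config$stroma_hole_px, protect)
  labels <- fill_holes_class(labels, class_code("ADIPOSE"),
                             config$adipose_hole_px, protect)
  labels <- fill_holes_class(labels, class_code("VESSEL"), Inf)
  label_map(labels, lm$pixel_size_um)
}

#' Full post-processing: smooth, vote, cascade
#'
#' @param stack Probability array from [predict_slide()].
#' @param pixel_size_um Pixel size of the image.
#' @param config A [postprocess_config()].
#' @return A cleaned [label_map()].
#' @export
postprocess <- function(stack, pixel_size_um = 0.5034,
                        config = postprocess_config()) {
  stack <- smooth_probabilities(stack, config$sigma)
  apply_cascade(vote(stack, pixel_size_um), config)
}
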