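#' Sliding-window whole-image prediction with centre-weighted blending
#'
#' The image is covered by overlapping tiles (default 512 px with 128 px
#' overlap, i.e. stride 384); the last row/column of windows is shifted so it
#' ends exactly at the image border. Each tile's class probabilities are
#' blended with weights that fall off linearly with the Chebyshev distance to
#' the tile centre, `w(x) = max(1 - d(x)/d_max, 1e-3)` — the floor keeps
#' pixels covered by a single tile from losing all mass at the tile border —
#' and the accumulated stack is renormalized per pixel. Images smaller than
#' one tile are mirror-padded and cropped back.
#'
#' @param image Array `[H, W, 3]` in \[0, 1\].
#' @param network An `angio_unet`, or any function mapping an
#'   `[h, w, 3]` array to an `[h, w, C]` probability array (useful for
#'   deterministic stubs).
#' @param tile_px Window edge (pixels).
#' @param overlap_px Overlap between adjacent windows; must be < `tile_px`.
#' @param n_classes Number of classes in the output stack.
#' @return Probability array `[H, W, n_classes]`; per-pixel sums are 1.
#' @export
predict_slide <- function(image, network, tile_px = 512, overlap_px = 128,
                          n_classes = 10) {
  stopifnot(length(dim(image)) == 3)
  if (overlap_px >= tile_px) stop("overlap must be smaller than the tile size")
  H0 <- dim(image)[1]; W0 <- dim(image)[2]
  img <- if (H0 < tile_px || W0 < tile_px) {
    pad_mirror(image, max(H0, tile_px), max(W0, tile_px))
  } else image
  H <- dim(img)[1]; W <- dim(img)[2]
  stride <- tile_px - overlap_px
  starts <- function(n) {
    s <- seq(1, max(n - tile_px + 1, 1), by = stride)
    unique(c(s, n - tile_px + 1))
  }
  fwd <- if (inherits(network, "angio_unet")) {
    function(x) predict(network, x)
  } else network

  ctr <- (tile_px + 1) / 2
  d <- outer(abs(seq_len(tile_px) - ctr), abs(seq_len(tile_px) - ctr), pmax)
  wtile <- pmax(1 - d / max(d), 1e-3)

  acc <- array(0, c(H, W, n_classes))
  wsum <- matrix(0, H, W)
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      rs <- r0:(r0 + tile_px - 1); cs <- c0:(c0 + tile_px - 1)
      p <- fwd(img[rs, cs, , drop = FALSE])
      for (j in seq_len(n_classes)) {
        acc[rs, cs, j] <- acc[rs, cs, j] + p[, , j] * wtile
      }
      wsum[rs, cs] <- wsum[rs, cs] + wtile
    }
  }
  for (j in seq_len(n_classes)) acc[, , j] <- acc[, , j] / wsum
  tot <- rowSums(matrix(acc, H * W, n_classes))
  for (j in seq_len(n_classes)) acc[, , j] <- acc[, , j] / tot
  acc[seq_len(H0), seq_len(W0), , drop = FALSE]
}

#' Per-pixel majority vote over a probability stack
#'
#' Assigns each pixel the class with the highest blended probability. Exact
#' ties are broken deterministically towards the lower class code.
#'
#' @param stack Probability array `[H, W, C]` from [predict_slide()].
#' @param pixel_size_um Pixel size for the resulting label map.
#' @return A [label_map()].
#' @export
vote <- function(stack, pixel_size_um = 0.5034) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  m <- matrix(stack, d[1] * d[2], d[3])
  label_map(matrix(max.col(m, ties.method = "first"), d[1], d[2]),
            pixel_size_um)
}
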