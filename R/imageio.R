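#' Read an RGB histology image
#'
#' Reads a PNG or TIFF image as a `[H, W, 3]` array in \[0, 1\]. The physical
#' pixel size is taken from the `pixel_size_um` override when given;
#' otherwise, for TIFF, from the embedded resolution tags. Grayscale images
#' are replicated to three channels; an alpha channel is dropped. Only
#' single-resolution images are handled; if a multi-page pyramid is supplied
#' the first (full-resolution) page is used.
#'
#' @param path Image file (.png, .tif, .tiff).
#' @param pixel_size_um Optional pixel edge length in microns, overriding any
#'   file metadata. The 20x acquisition value used throughout is 0.5034.
#' @return List with `image` (array `[H, W, 3]`), `pixel_size_um`,
#'   `width_px`, `height_px`.
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    if (is.list(img)) img <- img[[1]]
    if (is.null(pixel_size_um)) {
      res <- attr(img, "x.resolution")
      unit <- attr(img, "resolution.unit")
      if (!is.null(res) && is.finite(res) && res > 0) {
        per_unit_um <- switch(as.character(unit %||% "inch"),
                              "inch" = 25400, "2" = 25400,
                              "cm" = 10000, "3" = 10000, NA_real_)
        if (is.finite(per_unit_um)) pixel_size_um <- per_unit_um / res
      }
    }
  } else {
    stop("unreadable format: ", ext, " (use PNG or TIFF)")
  }
  if (is.null(pixel_size_um)) {
    stop("no pixel size in file metadata and no override supplied")
  }
  stopifnot(pixel_size_um > 0)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
  list(image = img, pixel_size_um = as.numeric(pixel_size_um),
       width_px = ncol(img), height_px = nrow(img))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a label map as an 8-bit grayscale PNG
#'
#' Class codes 1-10 are stored directly as gray levels (scaled by 1/255), so
#' the file round-trips exactly.
#'
#' @param lm A [label_map()].
#' @param path Output path.
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  png::writePNG(lm$labels / 255, path)
  invisible(path)
}

#' @rdname write_label_map
#' @param pixel_size_um Pixel size to attach on read.
#' @export
read_label_map <- function(path, pixel_size_um = 0.5034) {
  if (!file.exists(path)) stop("label map not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  label_map(matrix(as.integer(round(img * 255)), nrow(img)), pixel_size_um)
}

#' Read polygonal tissue annotations (GeoJSON)
#'
#' Reads a QuPath-style GeoJSON FeatureCollection. Each feature must carry
#' its tissue class in `properties.classification.name` (a bare
#' `properties.classification` string is also accepted) and a Polygon or
#' MultiPolygon geometry in pixel coordinates (x = column, y = row, 0-based
#' pixel centres).
#'
#' @param path GeoJSON file.
#' @return Tibble with `class` (name), `code`, and `rings` (list of numeric
#'   matrices, columns x/y; the first ring of a polygon is the exterior,
#'   later rings are holes).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (!is.null(js$features)) js$features else list(js)
  rows <- purrr::map(feats, function(f) {
    cls <- f$properties$classification
    name <- if (is.list(cls)) cls$name else cls
    if (is.null(name)) stop("feature without classification name")
    code <- class_code(name)  # errors on unknown class
    geom <- f$geometry
    polys <- switch(geom$type,
      "Polygon" = list(geom$coordinates),
      "MultiPolygon" = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    purrr::map(polys, function(poly) {
      rings <- purrr::map(poly, function(ring) {
        m <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
        colnames(m) <- c("x", "y")
        m
      })
      tibble::tibble(class = toupper(name), code = code, rings = list(rings))
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}

#' Default class precedence for overlapping annotations
#'
#' Highest first. Mirrors the post-processing overwrite protections: vessels
#' and leukocytes are never silently absorbed by surrounding region
#' annotations.
#' @return Character vector of class names, highest precedence first.
#' @export
class_precedence <- function() {
  c("VESSEL", "LEUKOCYTE", "NERVE", "MUSCLE", "LYMPHOCYTE",
    "TUMOUR", "BENIGN", "ADIPOSE", "STROMA", "BACKGROUND")
}

#' Rasterize polygon annotations to a label map
#'
#' Polygons are filled at pixel centres (even-odd rule, so holes in a polygon
#' stay open) and painted in increasing precedence order, so where
#' annotations overlap the higher-precedence class wins. Unannotated pixels
#' become stroma inside the tissue extent; when a `tissue_mask` is supplied,
#' pixels outside it (and outside any annotation) become background.
#'
#' @param annotations Tibble from [read_annotations()].
#' @param width_px,height_px Canvas size in pixels.
#' @param pixel_size_um Pixel size for the output map.
#' @param tissue_mask Optional logical matrix of the tissue extent.
#' @param precedence Class names, highest precedence first.
#' @return A [label_map()].
#' @export
rasterize_annotations <- function(annotations, width_px, height_px,
                                  pixel_size_um = 0.5034, tissue_mask = NULL,
                                  precedence = class_precedence()) {
  labels <- matrix(class_code("STROMA"), height_px, width_px)
  if (!is.null(tissue_mask)) labels[!tissue_mask] <- class_code("BACKGROUND")
  if (!is.null(annotations) && nrow(annotations)) {
    paint_order <- rev(precedence)
    for (cls in paint_order) {
      sel <- annotations$class == cls
      if (!any(sel)) next
      code <- class_code(cls)
      for (i in which(sel)) {
        rings <- annotations$rings[[i]]
        xs <- unlist(purrr::map(rings, ~ .x[, "x"]))
        ys <- unlist(purrr::map(rings, ~ .x[, "y"]))
        starts <- cumsum(c(0L, head(vapply(rings, nrow, integer(1)), -1)))
        m <- cpp_fill_polygon(xs, ys, as.integer(starts), height_px, width_px)
        labels[m] <- code
      }
    }
  }
  label_map(labels, pixel_size_um)
}

# mirror-pad an image (2d or 3d) on the right/bottom to at least (H, W)
pad_mirror <- function(x, H, W) {
  d <- dim(x)
  ri <- reflect_index(seq_len(max(H, d[1])), d[1])
  ci <- reflect_index(seq_len(max(W, d[2])), d[2])
  if (length(d) == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Cut an image and its label map into training tiles
#'
#' Tiles are laid on a regular grid of the given stride; images smaller than
#' the tile (or with a remainder at the right/bottom margin) are mirror-padded
#' so the tiling covers the full annotated region. Masks are one-hot over the
#' 10 tissue classes.
#'
#' @param image Array `[H, W, 3]`.
#' @param lm Matching [label_map()].
#' @param tile_px Tile edge in pixels.
#' @param stride_px Grid stride in pixels (default `tile_px`, non-overlapping).
#' @return Tibble with `row0`, `col0` (1-based tile origins in the padded
#'   frame) and list-columns `rgb`, `mask`, `labels`.
#' @export
extract_tiles <- function(image, lm, tile_px, stride_px = tile_px) {
  stopifnot(inherits(lm, "label_map"))
  if (tile_px <= 0 || stride_px <= 0) stop("tile and stride must be positive")
  if (!identical(dim(image)[1:2], dim(lm$labels))) stop("image/label dimensions differ")
  H0 <- nrow(lm$labels); W0 <- ncol(lm$labels)
  Hp <- max(H0, tile_px); Wp <- max(W0, tile_px)
  # extend so the stride grid covers the full extent
  n_r <- max(1, ceiling((Hp - tile_px) / stride_px) + 1)
  n_c <- max(1, ceiling((Wp - tile_px) / stride_px) + 1)
  Hp <- (n_r - 1) * stride_px + tile_px
  Wp <- (n_c - 1) * stride_px + tile_px
  img <- pad_mirror(image, Hp, Wp)
  lab <- pad_mirror(lm$labels, Hp, Wp)
  grid <- expand.grid(row0 = (seq_len(n_r) - 1) * stride_px + 1,
                      col0 = (seq_len(n_c) - 1) * stride_px + 1)
  purrr::map2(grid$row0, grid$col0, function(r0, c0) {
    rs <- r0:(r0 + tile_px - 1); cs <- c0:(c0 + tile_px - 1)
    lab_t <- lab[rs, cs, drop = FALSE]
    tibble::tibble(row0 = r0, col0 = c0,
                   rgb = list(img[rs, cs, , drop = FALSE]),
                   mask = list(one_hot(lab_t)),
                   labels = list(lab_t))
  }) |> purrr::list_rbind()
}

#' Write a measurement table to CSV
#'
#' One row per vessel or region; list-columns are dropped with a note since
#' CSV is flat. Row order is preserved, so output is deterministic.
#'
#' @param records A data frame (e.g. from [measure_vessels()]).
#' @param path Output CSV path.
#' @export
write_measurements <- function(records, path) {
  flat <- records[!vapply(records, is.list, logical(1))]
  ok <- tryCatch({ write.csv(flat, path, row.names = FALSE); TRUE },
                 error = function(e) stop("cannot write measurements: ",
                                          conditionMessage(e)))
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  tibble::as_tibble(read.csv(path))
}
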