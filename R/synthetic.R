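#' Configuration for the synthetic CD-31 scene generator
#'
#' The generator emulates the appearance of CD-31 IHC at 20x: DAB-brown
#' annular vessel walls (optionally fragmented, with unstained lumens),
#' hematoxylin-blue nuclei in tumour/benign nests and lymphocyte clusters,
#' white adipose vacuoles with thin septa, pink stroma, and near-white slide
#' background — together with an exact ground-truth label map. The vessel
#' ground truth is the *filled* vessel (wall plus lumen): annotations treat
#' vessels as filled objects and the post-processing hole filling restores
#' the lumen, so fragments and hollow centres exist in the RGB rendering
#' only, never in the truth.
#'
#' @param seed Integer; the same seed gives bit-identical output.
#' @param canvas_px Square canvas edge in pixels.
#' @param pixel_size_um Pixel size (microns); default the 20x acquisition
#'   value 0.5034.
#' @param n_vessels,n_tumour,n_benign,n_adipose,n_lymphocyte,n_nerve,n_muscle,n_leukocyte
#'   Structure counts (all >= 0).
#' @param vessel_outer_radius_px Range of outer semi-major radii (pixels).
#' @param vessel_wall_px Range of wall thicknesses (pixels).
#' @param vessel_elongation Range of major/minor axis ratios.
#' @param vessel_gap_prob Probability that a vessel wall is fragmented (in
#'   the rendering only).
#' @param vessel_shape `"ellipse"` or `"strip"` (rotated rectangle, used to
#'   calibrate width-sensitive measures).
#' @param background_band Draw an irregular background band along one edge.
#' @param blur_sigma,noise_sd Rendering blur (pixels) and additive RGB noise.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, canvas_px = 512, pixel_size_um = 0.5034,
                         n_vessels = 8, n_tumour = 2, n_benign = 1,
                         n_adipose = 5, n_lymphocyte = 2, n_nerve = 1,
                         n_muscle = 1, n_leukocyte = 3,
                         vessel_outer_radius_px = c(6, 16),
                         vessel_wall_px = c(3, 5),
                         vessel_elongation = c(1, 2.5),
                         vessel_gap_prob = 0.3,
                         vessel_shape = c("ellipse", "strip"),
                         background_band = TRUE,
                         blur_sigma = 0.5, noise_sd = 0.02) {
  counts <- c(n_vessels, n_tumour, n_benign, n_adipose, n_lymphocyte,
              n_nerve, n_muscle, n_leukocyte)
  if (any(counts < 0)) stop("structure counts must be >= 0")
  if (any(vessel_outer_radius_px <= 0) || any(vessel_wall_px <= 0)) {
    stop("vessel radius and wall ranges must be positive")
  }
  structure(list(seed = as.integer(seed), canvas_px = as.integer(canvas_px),
                 pixel_size_um = pixel_size_um,
                 n_vessels = n_vessels, n_tumour = n_tumour,
                 n_benign = n_benign, n_adipose = n_adipose,
                 n_lymphocyte = n_lymphocyte, n_nerve = n_nerve,
                 n_muscle = n_muscle, n_leukocyte = n_leukocyte,
                 vessel_outer_radius_px = vessel_outer_radius_px,
                 vessel_wall_px = vessel_wall_px,
                 vessel_elongation = vessel_elongation,
                 vessel_gap_prob = vessel_gap_prob,
                 vessel_shape = match.arg(vessel_shape),
                 background_band = isTRUE(background_band),
                 blur_sigma = blur_sigma, noise_sd = noise_sd),
            class = "synth_config")
}

# logical mask of a rotated ellipse (or strip) on an H x W canvas
shape_mask <- function(H, W, cy, cx, a, b, theta, shape = "ellipse") {
  r0 <- max(1, floor(cy - a - 2)); r1 <- min(H, ceiling(cy + a + 2))
  c0 <- max(1, floor(cx - a - 2)); c1 <- min(W, ceiling(cx + a + 2))
  out <- matrix(FALSE, H, W)
  if (r1 < r0 || c1 < c0) return(out)
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  m <- if (shape == "ellipse") (u / a)^2 + (v / b)^2 <= 1
       else abs(u) <= a & abs(v) <= b
  out[rr, cc] <- m
  out
}

synth_palette <- function() {
  list(BACKGROUND = c(0.97, 0.97, 0.97),
       STROMA = c(0.93, 0.77, 0.81),
       ADIPOSE = c(0.97, 0.96, 0.96),
       TUMOUR = c(0.80, 0.72, 0.88),
       BENIGN = c(0.86, 0.78, 0.88),
       LYMPHOCYTE = c(0.72, 0.70, 0.86),
       MUSCLE = c(0.88, 0.62, 0.66),
       NERVE = c(0.91, 0.80, 0.74),
       LEUKOCYTE = c(0.55, 0.36, 0.20),
       VESSEL_WALL = c(0.54, 0.33, 0.16),
       LUMEN = c(0.96, 0.95, 0.95),
       NUCLEUS = c(0.33, 0.28, 0.55))
}

stamp_dots <- function(rgb, mask, n, col, jitter = 0.04) {
  idx <- which(mask)
  if (!length(idx) || n < 1) return(rgb)
  pick <- idx[sample.int(length(idx), min(n, length(idx)))]
  H <- nrow(mask); W <- ncol(mask)
  r <- (pick - 1) %% H + 1; c <- (pick - 1) %/% H + 1
  for (dr in -1:1) for (dc in -1:1) {
    rr <- pmin(pmax(r + dr, 1), H); cc <- pmin(pmax(c + dc, 1), W)
    for (ch in 1:3) rgb[cbind(rr, cc, ch)] <- col[ch]
  }
  for (ch in 1:3) {
    rgb[cbind(r, c, ch)] <- col[ch] + rnorm(length(r), 0, jitter)
  }
  rgb
}

#' Generate one synthetic CD-31 scene
#'
#' Draws the configured structures onto a stroma canvas (vessels painted
#' last, with enforced vessel-vessel separation so ground-truth instances
#' equal connected components) and renders an RGB image that mimics the
#' stain: only the vessel *wall* is DAB-brown, the lumen is unstained, and
#' fragmented walls lose angular sectors in the rendering while the label map
#' keeps the filled vessel.
#'
#' @param config A [synth_config()].
#' @return List with `rgb` (array), `label_map` ([label_map()]), and
#'   `instances` (tibble of true vessel parameters: centre, semi-axes, wall,
#'   axis ratio, area, minor width).
#' @export
generate_scene <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  S <- config$canvas_px
  ps <- config$pixel_size_um
  pal <- synth_palette()
  labels <- matrix(class_code("STROMA"), S, S)

  if (config$background_band) {
    band <- pmax(2, round(S * 0.08 * (0.7 + 0.5 * sin(seq_len(S) / S * 4 * pi + runif(1, 0, 2 * pi)))))
    for (r in seq_len(S)) labels[r, seq_len(band[r])] <- class_code("BACKGROUND")
  }

  place <- function(n, rmin, rmax, elong = c(1, 2), shape = "ellipse") {
    purrr::map(seq_len(n), function(i) {
      a <- runif(1, rmin, rmax)
      b <- a / runif(1, elong[1], elong[2])
      list(cy = runif(1, a + 2, S - a - 1), cx = runif(1, a + 2, S - a - 1),
           a = a, b = b, theta = runif(1, 0, pi), shape = shape)
    })
  }
  paint <- function(labels, shapes, code) {
    for (s in shapes) {
      m <- shape_mask(S, S, s$cy, s$cx, s$a, s$b, s$theta, s$shape)
      labels[m & labels != class_code("BACKGROUND")] <- code
    }
    labels
  }

  sc <- S / 512  # structure sizes scale with the canvas
  adipose <- place(config$n_adipose, 10 * sc + 4, 26 * sc + 6, c(1, 1.4))
  labels <- paint(labels, adipose, class_code("ADIPOSE"))
  benign <- place(config$n_benign, 18 * sc + 6, 30 * sc + 8, c(1, 1.6))
  labels <- paint(labels, benign, class_code("BENIGN"))
  tumour <- purrr::map(seq_len(config$n_tumour), function(i) {
    ctr <- place(1, 30 * sc + 10, 48 * sc + 12, c(1, 1.5))[[1]]
    lobes <- purrr::map(seq_len(3), function(j) {
      l <- place(1, 14 * sc + 6, 26 * sc + 8, c(1, 1.6))[[1]]
      l$cy <- min(max(ctr$cy + rnorm(1, 0, ctr$a / 2), l$a + 2), S - l$a - 1)
      l$cx <- min(max(ctr$cx + rnorm(1, 0, ctr$a / 2), l$a + 2), S - l$a - 1)
      l
    })
    c(list(ctr), lobes)
  }) |> purrr::list_flatten()
  labels <- paint(labels, tumour, class_code("TUMOUR"))
  muscle <- place(config$n_muscle, 16 * sc + 6, 30 * sc + 8, c(3, 5))
  labels <- paint(labels, muscle, class_code("MUSCLE"))
  nerve <- place(config$n_nerve, 8 * sc + 4, 16 * sc + 6, c(1.5, 2.5))
  labels <- paint(labels, nerve, class_code("NERVE"))
  lymph <- place(config$n_lymphocyte, 10 * sc + 5, 22 * sc + 8, c(1, 1.5))
  labels <- paint(labels, lymph, class_code("LYMPHOCYTE"))
  leuko <- place(config$n_leukocyte, 2.5, 4.5, c(1, 1.3))
  labels <- paint(labels, leuko, class_code("LEUKOCYTE"))

  # vessels last: highest precedence, enforced mutual separation
  placed <- list()
  rr <- config$vessel_outer_radius_px
  for (i in seq_len(config$n_vessels)) {
    ok <- FALSE
    for (try in seq_len(300)) {
      a <- runif(1, rr[1], rr[2])
      b <- a / runif(1, config$vessel_elongation[1], config$vessel_elongation[2])
      wall <- runif(1, config$vessel_wall_px[1], config$vessel_wall_px[2])
      b <- max(b, wall + 1.5)  # a lumen must fit
      if (S - 2 * a - 4 < 2) break
      cy <- runif(1, a + 2, S - a - 1); cx <- runif(1, a + 2, S - a - 1)
      sep <- vapply(placed, function(p) {
        sqrt((p$cy - cy)^2 + (p$cx - cx)^2) > p$a + a + 4
      }, logical(1))
      if (all(sep)) {
        placed[[length(placed) + 1L]] <- list(cy = cy, cx = cx, a = a, b = b,
                                              wall = wall,
                                              theta = runif(1, 0, pi))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("canvas too small for requested structures (vessel placement failed)")
  }

  instances <- purrr::imap(placed, function(p, i) {
    m <- shape_mask(S, S, p$cy, p$cx, p$a, p$b, p$theta, config$vessel_shape)
    labels[m] <<- class_code("VESSEL")
    tibble::tibble(vessel_id = i, centre_row = p$cy, centre_col = p$cx,
                   semi_major_px = p$a, semi_minor_px = p$b,
                   angle = p$theta, wall_px = p$wall,
                   shape = config$vessel_shape,
                   axis_ratio = p$a / p$b, area_px = sum(m),
                   width_px = 2 * p$b,
                   fragmented = FALSE)
  }) |> purrr::list_rbind()

  # ---- rendering -----------------------------------------------------------
  rgb <- array(0, c(S, S, 3))
  for (cls in c("BACKGROUND", "STROMA", "ADIPOSE", "TUMOUR", "BENIGN",
                "LYMPHOCYTE", "MUSCLE", "NERVE", "LEUKOCYTE")) {
    m <- labels == class_code(cls)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[m] <- pal[[cls]][ch]
      rgb[, , ch] <- plane
    }
  }
  # adipose septa: thin pink rims around vacuoles
  adi <- labels == class_code("ADIPOSE")
  rim <- adi & !(adi[c(1, seq_len(S - 1)), ] & adi[c(seq_len(S - 1) + 1, S), ] &
                 adi[, c(1, seq_len(S - 1))] & adi[, c(seq_len(S - 1) + 1, S)])
  for (ch in 1:3) {
    plane <- rgb[, , ch]; plane[rim] <- pal$STROMA[ch]; rgb[, , ch] <- plane
  }
  # nuclei dots
  rgb <- stamp_dots(rgb, labels == class_code("TUMOUR"),
                    round(sum(labels == class_code("TUMOUR")) * 0.02),
                    pal$NUCLEUS)
  rgb <- stamp_dots(rgb, labels == class_code("BENIGN"),
                    round(sum(labels == class_code("BENIGN")) * 0.012),
                    pal$NUCLEUS + 0.08)
  rgb <- stamp_dots(rgb, labels == class_code("LYMPHOCYTE"),
                    round(sum(labels == class_code("LYMPHOCYTE")) * 0.05),
                    c(0.25, 0.22, 0.50))

  # vessel walls and lumens (rendering only; truth stays filled)
  if (length(placed)) {
    n_frag <- 0L
    for (i in seq_along(placed)) {
      p <- placed[[i]]
      outer <- shape_mask(S, S, p$cy, p$cx, p$a, p$b, p$theta, config$vessel_shape)
      inner <- shape_mask(S, S, p$cy, p$cx, max(p$a - p$wall, 0.5),
                          max(p$b - p$wall, 0.5), p$theta, config$vessel_shape)
      wallm <- outer & !inner
      frag <- runif(1) < config$vessel_gap_prob
      gapm <- matrix(FALSE, S, S)
      if (frag) {
        n_gaps <- sample(1:2, 1)
        idx <- which(wallm)
        wr <- (idx - 1) %% S + 1; wc <- (idx - 1) %/% S + 1
        ang <- atan2(wr - p$cy, wc - p$cx)
        for (gi in seq_len(n_gaps)) {
          a0 <- runif(1, -pi, pi); wdt <- runif(1, 20, 60) * pi / 180
          dd <- ((ang - a0 + pi) %% (2 * pi)) - pi
          gapm[idx[abs(dd) < wdt / 2]] <- TRUE
        }
        instances$fragmented[i] <- TRUE
        n_frag <- n_frag + 1L
      }
      jit <- rnorm(sum(wallm), 0, 0.03)
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[inner] <- pal$LUMEN[ch]
        plane[wallm] <- pal$VESSEL_WALL[ch] + jit
        plane[gapm] <- pal$STROMA[ch]
        rgb[, , ch] <- plane
      }
    }
  }

  if (config$noise_sd > 0) rgb <- rgb + rnorm(length(rgb), 0, config$noise_sd)
  if (config$blur_sigma > 0) {
    for (ch in 1:3) rgb[, , ch] <- EBImage::gblur(rgb[, , ch], config$blur_sigma)
  }
  rgb <- pmin(pmax(rgb, 0), 1)

  list(rgb = rgb, label_map = label_map(labels, ps), instances = instances)
}

#' Generate a set of training tiles in memory
#'
#' Tile `i` uses seed `config$seed + i - 1`, so any tile can be regenerated
#' independently and the whole set is reproducible.
#'
#' @param config A [synth_config()] (use a small `canvas_px` for tiles).
#' @param n_tiles Number of tiles.
#' @return Tibble with `tile` and list-columns `rgb`, `mask` (one-hot),
#'   `labels`, `instances` — directly consumable by [train_unet()].
#' @export
generate_tiles <- function(config = synth_config(canvas_px = 64), n_tiles = 8) {
  purrr::map(seq_len(n_tiles), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sc <- generate_scene(cfg)
    tibble::tibble(tile = i, rgb = list(sc$rgb),
                   mask = list(one_hot(sc$label_map)),
                   labels = list(sc$label_map$labels),
                   instances = list(sc$instances))
  }) |> purrr::list_rbind()
}

#' Write a synthetic tile dataset to disk
#'
#' Emits `img_###.png` / `lab_###.png` pairs plus a JSON manifest of the
#' ground-truth vessel instances and the per-class pixel balance.
#'
#' @param config A [synth_config()].
#' @param n_tiles Number of tiles.
#' @param dir Output directory (created if missing).
#' @return The manifest as a tibble, invisibly.
#' @export
generate_dataset <- function(config, n_tiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tiles <- generate_tiles(config, n_tiles)
  balance <- matrix(0L, n_tiles, 10)
  for (i in seq_len(n_tiles)) {
    png::writePNG(tiles$rgb[[i]], file.path(dir, sprintf("img_%03d.png", i)))
    png::writePNG(tiles$labels[[i]] / 255, file.path(dir, sprintf("lab_%03d.png", i)))
    balance[i, ] <- tabulate(tiles$labels[[i]], 10L)
  }
  colnames(balance) <- tissue_classes()$name
  manifest <- list(
    pixel_size_um = config$pixel_size_um,
    seed = config$seed,
    n_tiles = n_tiles,
    class_balance_px = colSums(balance),
    tiles = purrr::map(seq_len(n_tiles), function(i) {
      list(image = sprintf("img_%03d.png", i),
           labels = sprintf("lab_%03d.png", i),
           instances = tiles$instances[[i]])
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf("wrote %d tiles; class balance (px): %s", n_tiles,
                  paste(sprintf("%s=%d", colnames(balance), colSums(balance)),
                        collapse = " ")))
  invisible(tiles)
}
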