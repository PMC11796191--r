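# reflect a (possibly out-of-range) 1-based index into 1..n
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- (i - 1) %% (2 * n - 2)
  as.integer(round(n - abs(p - (n - 1))))
}

# rotate a matrix about its centre by `angle` degrees; out-of-frame samples
# are taken from the mirror-padded extension of the image
rotate_mirror <- function(m, angle, bilinear = TRUE) {
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  dr <- g$r - cr; dc <- g$c - cc
  # inverse rotation of destination coordinates
  sr <- cr + cos(th) * dr + sin(th) * dc
  sc <- cc - sin(th) * dr + cos(th) * dc
  if (!bilinear) {
    ri <- reflect_index(round(sr), H)
    ci <- reflect_index(round(sc), W)
    return(matrix(m[cbind(ri, ci)], H, W))
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(reflect_index(r0, H), reflect_index(c0, W))
  i10 <- cbind(reflect_index(r0 + 1, H), reflect_index(c0, W))
  i01 <- cbind(reflect_index(r0, H), reflect_index(c0 + 1, W))
  i11 <- cbind(reflect_index(r0 + 1, H), reflect_index(c0 + 1, W))
  v <- m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
  matrix(v, H, W)
}

# vectorized hsv -> rgb (h, s, v in [0,1]); returns 3 x n matrix
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Data augmentation for one training tile
#'
#' Applies, in order: a random horizontal and vertical flip, a random
#' rotation (sampling outside the frame from the mirror-padded image, so no
#' empty corners are introduced), and color jitter on the RGB channels only.
#' Geometric transforms are applied identically to image and mask; the mask
#' is resampled nearest-neighbour so it stays strictly one-hot.
#'
#' @param rgb Array `[H, W, 3]` in \[0, 1\].
#' @param mask One-hot array `[H, W, C]`.
#' @param flip_prob Probability of each flip.
#' @param max_angle Rotation drawn uniformly from `[-max_angle, max_angle]`
#'   degrees.
#' @param brightness,contrast,saturation Jitter amplitudes (multiplicative /
#'   additive fractions).
#' @param hue Hue shift amplitude (fraction of the hue circle).
#' @return List with jittered `rgb` and transformed one-hot `mask`.
#' @export
augment_tile <- function(rgb, mask, flip_prob = 0.5, max_angle = 180,
                         brightness = 0.1, contrast = 0.1, saturation = 0.1,
                         hue = 0.02) {
  stopifnot(length(dim(rgb)) == 3, length(dim(mask)) == 3)
  C <- dim(mask)[3]
  labels <- apply(mask, c(1, 2), which.max)
  if (runif(1) < flip_prob) {
    rgb <- rgb[nrow(labels):1, , , drop = FALSE]
    labels <- labels[nrow(labels):1, , drop = FALSE]
  }
  if (runif(1) < flip_prob) {
    rgb <- rgb[, ncol(labels):1, , drop = FALSE]
    labels <- labels[, ncol(labels):1, drop = FALSE]
  }
  angle <- runif(1, -max_angle, max_angle)
  if (abs(angle) > 1e-9) {
    for (ch in 1:3) rgb[, , ch] <- rotate_mirror(rgb[, , ch], angle, bilinear = TRUE)
    labels <- rotate_mirror(labels, angle, bilinear = FALSE)
  }
  # color jitter on rgb only
  rgb <- rgb + runif(1, -brightness, brightness)
  mu <- mean(rgb)
  rgb <- (rgb - mu) * (1 + runif(1, -contrast, contrast)) + mu
  gray <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  fs <- 1 + runif(1, -saturation, saturation)
  for (ch in 1:3) rgb[, , ch] <- gray + (rgb[, , ch] - gray) * fs
  rgb <- pmin(pmax(rgb, 0), 1)
  dh <- runif(1, -hue, hue)
  if (abs(dh) > 0) {
    d <- dim(rgb)
    cols <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
    hsv <- grDevices::rgb2hsv(cols, maxColorValue = 1)
    out <- hsv_to_rgb(hsv[1, ] + dh, hsv[2, ], hsv[3, ])
    rgb <- array(c(out[1, ], out[2, ], out[3, ]), d)
  }
  rgb <- pmin(pmax(rgb, 0), 1)
  list(rgb = rgb, mask = one_hot(matrix(as.integer(labels), nrow(labels)), C))
}
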