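# shared fixtures and independent oracles, built in code at test time

# digital disk of radius r embedded as class `fg` on a stroma canvas
fixture_disk <- function(r, fg = 1L, bg = 9L, margin = 5L) {
  S <- 2L * r + 2L * margin
  g <- expand.grid(seq_len(S), seq_len(S))
  ctr <- (S + 1) / 2
  m <- matrix(bg, S, S)
  m[(g[, 1] - ctr)^2 + (g[, 2] - ctr)^2 <= r^2] <- fg
  m
}

# axis-aligned rectangle of pixels as class `fg`
fixture_rect <- function(h, w, fg = 1L, bg = 9L, margin = 5L) {
  m <- matrix(bg, h + 2L * margin, w + 2L * margin)
  m[margin + seq_len(h), margin + seq_len(w)] <- fg
  m
}

# annulus with lumen labelled `lumen` (outer radius r_out, inner r_in)
fixture_annulus <- function(r_out, r_in, fg = 1L, lumen = 9L, bg = 9L,
                            margin = 5L) {
  S <- 2L * r_out + 2L * margin
  ctr <- (S + 1) / 2
  g <- expand.grid(seq_len(S), seq_len(S))
  d2 <- (g[, 1] - ctr)^2 + (g[, 2] - ctr)^2
  m <- matrix(bg, S, S)
  m[d2 <= r_out^2] <- fg
  m[d2 <= r_in^2] <- lumen
  m
}

# random blob: union of a few random ellipses on an S x S logical canvas
random_blob <- function(S = 96) {
  m <- matrix(FALSE, S, S)
  for (k in seq_len(sample(2:4, 1))) {
    a <- runif(1, S / 10, S / 4)
    b <- runif(1, S / 14, a)
    th <- runif(1, 0, pi)
    cy <- runif(1, a + 2, S - a - 1)
    cx <- runif(1, a + 2, S - a - 1)
    g <- expand.grid(seq_len(S), seq_len(S))
    dy <- g[, 1] - cy; dx <- g[, 2] - cx
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    m[(u / a)^2 + (v / b)^2 <= 1] <- TRUE
  }
  # keep the blob clear of the border so the mask frame is its own padding
  m[c(1, S), ] <- FALSE
  m[, c(1, S)] <- FALSE
  m
}

# brute-force local thickness: for every object pixel, the largest disk
# (centred anywhere) that contains it and fits inside the mask. Distances
# are computed by explicit enumeration -- no distance transform, no pruning.
bf_local_thickness <- function(mask) {
  obj <- which(mask)
  bgp <- which(!mask)
  H <- nrow(mask)
  orc <- cbind((obj - 1) %% H + 1, (obj - 1) %/% H + 1)
  brc <- cbind((bgp - 1) %% H + 1, (bgp - 1) %/% H + 1)
  # radius of the largest disk centred at each object pixel
  D <- vapply(seq_along(obj), function(i) {
    sqrt(min((brc[, 1] - orc[i, 1])^2 + (brc[, 2] - orc[i, 2])^2))
  }, numeric(1))
  th <- numeric(length(obj))
  for (i in seq_along(obj)) {
    d2 <- (orc[, 1] - orc[i, 1])^2 + (orc[, 2] - orc[i, 2])^2
    covered <- d2 < D^2   # centre c covers pixel i iff |x - c| < D(c)
    th[i] <- max(D[covered])
  }
  out <- matrix(0, nrow(mask), ncol(mask))
  out[obj] <- th
  out
}

# independent unweighted mean soft Dice complement (plain loops)
bf_mean_soft_dice_loss <- function(p, g) {
  C <- dim(p)[3]
  dice <- numeric(C)
  for (j in seq_len(C)) {
    num <- 2 * sum(p[, , j] * g[, , j])
    den <- sum(p[, , j]) + sum(g[, , j])
    dice[j] <- if (den == 0) 1 else num / den
  }
  1 - mean(dice)
}

# brute-force instance matcher: exhaustive overlap table and exhaustive
# maximum one-to-one matching over qualifying (coverage > frac) pairs
bf_detect <- function(true_id, pred_id, frac = 0.5) {
  n_true <- max(true_id); n_pred <- max(pred_id)
  if (n_true == 0) return(NULL)
  ov <- matrix(0L, max(n_true, 1), max(n_pred, 1))
  for (i in seq_along(true_id)) {
    ti <- true_id[i]; pj <- pred_id[i]
    if (ti > 0 && pj > 0) ov[ti, pj] <- ov[ti, pj] + 1L
  }
  tsize <- vapply(seq_len(n_true), function(t) sum(true_id == t), integer(1))
  qual <- which(ov / tsize > frac, arr.ind = TRUE)
  # recursive exhaustive maximum matching
  best <- 0L
  recurse <- function(k, used_t, used_p, count) {
    if (count + (nrow(qual) - k + 1) <= best) return()
    if (k > nrow(qual)) { best <<- max(best, count); return() }
    ti <- qual[k, 1]; pj <- qual[k, 2]
    if (!(ti %in% used_t) && !(pj %in% used_p)) {
      recurse(k + 1, c(used_t, ti), c(used_p, pj), count + 1L)
    }
    recurse(k + 1, used_t, used_p, count)
  }
  if (nrow(qual)) recurse(1L, integer(0), integer(0), 0L) else best <- 0L
  tp <- best
  list(tp = tp, fp = n_pred - tp, fn = n_true - tp,
       precision = if (n_pred > 0) tp / n_pred else NA_real_,
       recall = tp / n_true)
}

# random instance scene: a label matrix of blobs, plus a perturbed partner
random_instance_scene <- function(S = 64) {
  truth <- matrix(9L, S, S)
  n <- sample(2:5, 1)
  for (k in seq_len(n)) {
    r <- sample(3:7, 1)
    cy <- sample((r + 2):(S - r - 1), 1)
    cx <- sample((r + 2):(S - r - 1), 1)
    g <- expand.grid(seq_len(S), seq_len(S))
    truth[(g[, 1] - cy)^2 + (g[, 2] - cx)^2 <= r^2] <- 1L
  }
  # perturbed prediction: random shift, plus occasional extra/missing blobs
  dy <- sample(-3:3, 1); dx <- sample(-3:3, 1)
  pred <- matrix(9L, S, S)
  src_r <- pmin(pmax(seq_len(S) - dy, 1), S)
  src_c <- pmin(pmax(seq_len(S) - dx, 1), S)
  pred <- truth[src_r, src_c]
  if (runif(1) < 0.4) {  # spurious prediction
    r <- sample(3:5, 1)
    cy <- sample((r + 2):(S - r - 1), 1); cx <- sample((r + 2):(S - r - 1), 1)
    g <- expand.grid(seq_len(S), seq_len(S))
    pred[(g[, 1] - cy)^2 + (g[, 2] - cx)^2 <= r^2] <- 1L
  }
  if (runif(1) < 0.4) {  # erase part of the prediction
    pred[seq_len(sample.int(S, 1)), ] <- 9L
  }
  list(truth = truth, pred = pred)
}

# small synthetic tile configuration shared by the learning tests
toy_tile_config <- function(seed) {
  synth_config(seed = seed, canvas_px = 64, n_vessels = 2, n_tumour = 1,
               n_benign = 1, n_adipose = 1, n_lymphocyte = 1, n_nerve = 0,
               n_muscle = 0, n_leukocyte = 1,
               vessel_outer_radius_px = c(5, 10),
               vessel_wall_px = c(2.5, 3.5))
}

# random probability stack (valid categorical per pixel) and one-hot truth
random_loss_pair <- function(h = 6, w = 6, C = 4) {
  p <- array(runif(h * w * C), c(h, w, C))
  tot <- apply(p, c(1, 2), sum)
  for (j in seq_len(C)) p[, , j] <- p[, , j] / tot
  g <- angioquant::one_hot(matrix(sample.int(C, h * w, TRUE), h), C)
  list(p = p, g = g)
}
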