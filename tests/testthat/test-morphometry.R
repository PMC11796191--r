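test_that("vessel instances use 8-connectivity and the 40 px size filter", {
  lab <- matrix(9L, 40, 40)
  lab[2:11, 2:11] <- 1L      # 100 px
  lab[20:29, 20:29] <- 1L    # 100 px, disjoint
  lm <- label_map(lab, 1)
  expect_equal(nrow(label_vessels(lm)), 2)

  # 39 px blob is discarded
  lab2 <- matrix(9L, 20, 20)
  lab2[4:16, 4:6] <- 1L      # 39 px
  expect_equal(nrow(label_vessels(label_map(lab2, 1))), 0)
  expect_equal(nrow(label_vessels(label_map(lab2, 1), min_area_px = 39)), 1)

  # diagonal touch joins components under 8-connectivity
  lab3 <- matrix(9L, 30, 30)
  lab3[2:11, 2:11] <- 1L
  lab3[12:21, 12:21] <- 1L   # touches only at the diagonal corner
  expect_equal(nrow(label_vessels(label_map(lab3, 1))), 1)
})

test_that("areas scale with the squared pixel size", {
  expect_equal(measure_area(100, 0.5034), 25.34, tolerance = 1e-3)
  expect_equal(round(measure_area(40, 0.5034), 1), 10.1)  # ~10 um^2
  expect_equal(measure_area(1, 1), 1)
})

test_that("circularity anchors: analytic circle 1, analytic square pi/4", {
  r <- runif(1, 1, 50)
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  s <- runif(1, 1, 50)
  expect_equal(circularity(s^2, 4 * s, clip = FALSE), pi / 4)
})

test_that("measured circularity of digital shapes approaches the anchors", {
  lab <- fixture_disk(50)
  v <- measure_vessels(label_map(lab, 1))
  expect_equal(v$circularity, 1, tolerance = 0.05)
  expect_equal(v$axis_ratio, 1, tolerance = 0.05)

  labsq <- fixture_rect(40, 40)
  vsq <- measure_vessels(label_map(labsq, 1))
  expect_equal(vsq$circularity, pi / 4, tolerance = 0.05)
})

test_that("axis ratio of rectangles is exact and rotation-invariant", {
  v <- measure_vessels(label_map(fixture_rect(20, 40), 1))
  expect_equal(v$axis_ratio, 2, tolerance = 1e-9)

  # the same rectangle rotated 30 degrees, rasterized
  S <- 100; th <- 30 * pi / 180
  g <- expand.grid(seq_len(S), seq_len(S))
  u <- (g[, 2] - 50.5) * cos(th) + (g[, 1] - 50.5) * sin(th)
  w <- -(g[, 2] - 50.5) * sin(th) + (g[, 1] - 50.5) * cos(th)
  lab <- matrix(9L, S, S)
  lab[abs(u) <= 20 & abs(w) <= 10] <- 1L
  vr <- measure_vessels(label_map(lab, 1))
  expect_equal(vr$axis_ratio, 2, tolerance = 0.1)
})

test_that("thickness recovers strip widths and disk radii", {
  m <- matrix(FALSE, 40, 90); m[16:25, 6:85] <- TRUE  # 10 px wide strip
  th <- measure_thickness(which(m), dim(m), pixel_size_um = 1)
  expect_equal(th, 5, tolerance = 0.15)  # mean local radius ~ half width
  expect_equal(measure_thickness(which(m), dim(m), 1, scale = "diameter"),
               2 * th)

  disk <- fixture_disk(20) == 1L
  thd <- measure_thickness(which(disk), dim(disk), 1)
  d <- as.matrix(EBImage::distmap(disk * 1))
  expect_gt(thd, 0)
  expect_lte(thd, max(d) + 1e-9)
  oracle <- bf_local_thickness(disk)
  expect_equal(thd, mean(oracle[disk]), tolerance = 0.05)
})

test_that("sphere-fitting thickness matches the brute-force oracle on random blobs", {
  set.seed(21)
  rel_err <- replicate(12, {
    m <- random_blob(S = sample(48:96, 1))
    if (sum(m) < 30) return(NA_real_)
    impl <- measure_thickness(which(m), dim(m), 1)
    oracle <- mean(bf_local_thickness(m)[m])
    abs(impl - oracle) / oracle
  })
  rel_err <- rel_err[!is.na(rel_err)]
  expect_gt(length(rel_err), 5)
  expect_lt(mean(rel_err), 0.05)
})

test_that("density divides counts by stromal area within the region", {
  lab <- matrix(9L, 100, 100)   # 10^4 px at 10 um pixel = 1 mm^2 of stroma
  lab[11:20, 11:20] <- 1L
  lab[41:50, 41:50] <- 1L
  lm <- label_map(lab, 10)
  vs <- label_vessels(lm)
  region <- matrix(TRUE, 100, 100)
  stroma_mm2 <- sum(lab == 9L) * (10 / 1000)^2
  expect_equal(measure_density(vs, region, lm), 2 / stroma_mm2)
  # no vessels: zero density, not an error
  expect_equal(measure_density(vs[0, ], region, lm), 0 / stroma_mm2)
  # a region with no stromal pixels reports missing
  vonly <- lab == 1L
  expect_true(is.na(measure_density(vs, vonly & lab == 1L, lm)))
  expect_error(measure_density(vs, matrix(FALSE, 100, 100), lm), "empty")
})

test_that("doubling the stromal area halves the density", {
  lab <- matrix(10L, 60, 120)
  lab[, 1:60] <- 9L
  lab[11:16, 11:16] <- 1L
  lm <- label_map(lab, 5)
  vs <- label_vessels(lm, min_area_px = 10)
  half <- cbind(matrix(TRUE, 60, 60), matrix(FALSE, 60, 60))
  d1 <- measure_density(vs, half, lm)
  # append a second half whose stromal area equals the first half's exactly
  lab2 <- lab; lab2[, 61:120] <- 9L; lab2[11:16, 71:76] <- 10L
  lm2 <- label_map(lab2, 5)
  d2 <- measure_density(label_vessels(lm2, 10), matrix(TRUE, 60, 120), lm2)
  expect_equal(d2, d1 / 2)
})

test_that("summaries average per-vessel values and flag empty regions", {
  lab <- matrix(9L, 60, 60)
  lab[2:11, 2:11] <- 1L
  lab[30:39, 30:49] <- 1L
  lm <- label_map(lab, 1)
  mv <- measure_vessels(lm, min_area_px = 40)
  sm <- summarize_vessels(mv, lm = lm)
  expect_equal(sm$n_vessels, 2)
  expect_equal(sm$mean_area_um2, mean(mv$area_um2))
  one <- summarize_vessels(mv, region_mask = row(lab) < 20, lm = lm)
  expect_equal(one$n_vessels, 1)
  expect_equal(one$mean_axis_ratio, mv$axis_ratio[1])
  empty <- summarize_vessels(mv, region_mask = row(lab) > 55, lm = lm)
  expect_equal(empty$n_vessels, 0)
  expect_true(is.na(empty$mean_area_um2))
})

test_that("total instance area equals the filtered vessel pixel count", {
  set.seed(31)
  sc <- generate_scene(synth_config(seed = 17, canvas_px = 192, n_vessels = 4))
  lm <- sc$label_map
  mv <- measure_vessels(lm, min_area_px = 40)
  kept_px <- sum(mv$n_px)
  expect_equal(sum(mv$area_um2), kept_px * lm$pixel_size_um^2)
  # conservation against the raw vessel plane less discarded small components
  all_inst <- label_vessels(lm, min_area_px = 1)
  expect_lte(kept_px, sum(lm$labels == 1L))
  expect_equal(sum(all_inst$n_px), sum(lm$labels == 1L))
})

test_that("parameters are invariant to translation", {
  lab <- matrix(9L, 80, 80)
  g <- expand.grid(1:80, 1:80)
  lab[(g[, 1] - 25)^2 + (g[, 2] - 25)^2 <= 144] <- 1L
  lab2 <- matrix(9L, 80, 80)
  lab2[(g[, 1] - 55)^2 + (g[, 2] - 50)^2 <= 144] <- 1L
  v1 <- measure_vessels(label_map(lab, 1))
  v2 <- measure_vessels(label_map(lab2, 1))
  for (cl in c("n_px", "area_um2", "perimeter_um", "circularity",
               "axis_ratio", "thickness_um")) {
    expect_equal(v1[[cl]], v2[[cl]], tolerance = 1e-9)
  }
})
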