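region_toy_map <- function(gap_px, S = 560, ps = 1) {
  lab <- matrix(9L, S, S)
  lab[200:260, 50:110] <- 3L
  lab[200:260, (110 + gap_px + 1):(110 + gap_px + 61)] <- 5L
  label_map(lab, ps)
}

test_that("distant tumour and adipose blobs each grow the full dilation", {
  lm <- region_toy_map(gap_px = 340)  # centres ~400 um apart at 1 um px
  pt <- partition_regions(lm, dilation_um = 150, step_um = 5,
                          min_region_px = 1000)
  expect_false(any(pt$tumour & pt$adipose))
  d <- angioquant:::dist_to_mask(lm$labels == 3L)
  # pixels well inside 150 um of the tumour belong to the tumour region
  # (incremental growth reaches slightly under the nominal total along
  # directions where 5 px steps do not chain to exact Euclidean distance)
  expect_true(all(pt$tumour[d <= 140]))
  expect_true(all(!pt$tumour[d > 152]))
  # partition covers the tissue exactly
  expect_true(all((pt$tumour | pt$adipose | pt$stroma) ==
                    (lm$labels != 10L)))
})

test_that("close blobs meet near the midline without overlap", {
  lm <- region_toy_map(gap_px = 150)
  pt <- partition_regions(lm, 150, 5, 1000)
  expect_false(any(pt$tumour & pt$adipose))
  # the gap strip is fully claimed by one of the two regions
  gap <- matrix(FALSE, 560, 560); gap[200:260, 111:260] <- TRUE
  expect_true(all(pt$tumour[gap] | pt$adipose[gap]))
  # the meeting front lies near the equidistant midline
  dt <- angioquant:::dist_to_mask(lm$labels == 3L)
  da <- angioquant:::dist_to_mask(lm$labels == 5L)
  interior <- gap & abs(dt - da) > 12
  expect_true(all(pt$tumour[interior & dt < da]))
  expect_true(all(pt$adipose[interior & da < dt]))
})

test_that("sub-threshold seed components contribute no region", {
  lab <- matrix(9L, 200, 200)
  lab[50:79, 50:79] <- 3L  # 900 px < 1000
  pt <- partition_regions(label_map(lab, 1), 150, 5, 1000)
  expect_equal(sum(pt$tumour), 0)
  expect_true(all(pt$stroma == (lab != 10L)))
})

test_that("swapping tumour/adipose swaps the regions away from the meeting front", {
  # strict alternation (tumour grows first) is order-asymmetric exactly at
  # the contested front, so the swapped partition must agree everywhere
  # except within a couple of growth increments of the equidistant line
  lm <- region_toy_map(gap_px = 150)
  swapped <- lm$labels
  swapped[lm$labels == 3L] <- 5L
  swapped[lm$labels == 5L] <- 3L
  pt <- partition_regions(lm, 150, 5, 1000)
  pt_sw <- partition_regions(label_map(swapped[, ncol(swapped):1], 1), 150, 5, 1000)
  mir <- function(m) m[, ncol(m):1]
  dt <- angioquant:::dist_to_mask(lm$labels == 3L)
  da <- angioquant:::dist_to_mask(lm$labels == 5L)
  disagree <- (pt$tumour != mir(pt_sw$adipose)) | (pt$adipose != mir(pt_sw$tumour))
  expect_true(all(abs(dt - da)[disagree] <= 10))  # within 2 x 5 px steps
  far <- abs(dt - da) > 10
  expect_identical(pt$tumour[far], mir(pt_sw$adipose)[far])
  expect_identical(pt$adipose[far], mir(pt_sw$tumour)[far])
})

test_that("invalid dilation steps are rejected", {
  lm <- region_toy_map(150)
  expect_error(partition_regions(lm, 150, 0), "step_um")
  expect_error(partition_regions(lm, 150, 200), "step_um")
})

test_that("distance rings are disjoint annuli matching the distance transform", {
  lab <- matrix(9L, 300, 300)
  g <- expand.grid(1:300, 1:300)
  seed <- matrix((g[, 1] - 150)^2 + (g[, 2] - 150)^2 <= 100^2, 300, 300)
  lab[seed] <- 3L
  lm <- label_map(lab, 1)
  rs <- distance_rings(seed, lm, ring_width_um = 50, n_rings = 2)
  d <- angioquant:::dist_to_mask(seed)
  for (k in 1:2) {
    expect_identical(rs$rings[[k]], d > (k - 1) * 50 & d <= k * 50)
  }
  expect_false(any(rs$rings[[1]] & rs$rings[[2]]))
  # union of n rings = all tissue within n*w of the seed (seed excluded)
  un <- rs$rings[[1]] | rs$rings[[2]]
  expect_identical(un, d > 0 & d <= 100)
  expect_error(distance_rings(matrix(FALSE, 5, 5), lm), "empty")
})

test_that("lymphocyte percentage follows its definition", {
  lab <- matrix(10L, 20, 20)
  lab[1:10, 1:10] <- 9L
  lab[1:10, 11:13] <- 6L
  lm <- label_map(lab, 1)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(lymphocyte_percentage(mask, lm), 100 * 30 / 130)
  lab2 <- lab; lab2[lab2 == 6L] <- 9L
  expect_equal(lymphocyte_percentage(mask, label_map(lab2, 1)), 0)
  lab3 <- lab; lab3[lab3 == 9L] <- 6L
  expect_equal(lymphocyte_percentage(mask, label_map(lab3, 1)), 100)
  # no stromal compartment: missing
  expect_true(is.na(lymphocyte_percentage(lab == 10L, lm)))
})

test_that("vessel ring profiles report empty rings as missing", {
  lab <- matrix(9L, 200, 200)
  lab[95:105, 95:105] <- 3L
  lab[110:121, 95:106] <- 1L  # vessel in ring 1 (adjacent to tumour)
  lm <- label_map(lab, 1)
  vs <- measure_vessels(lm, min_area_px = 40)
  rs <- distance_rings(lab == 3L, lm, ring_width_um = 20, n_rings = 4)
  pr <- vessels_by_distance(vs, rs, lm)
  expect_equal(pr$n_vessels[1], 1)
  expect_true(all(pr$n_vessels[2:4] == 0))
  expect_true(all(pr$density_per_mm2[2:4] == 0))
  expect_true(all(is.na(pr$mean_area_um2[2:4])))
})

test_that("composition metrics follow their definitions", {
  lab <- matrix(10L, 40, 40)
  lab[1:20, 1:30] <- 3L
  lab[1:20, 31:40] <- 9L
  lm <- label_map(lab, 1)
  pt <- structure(list(tumour = matrix(TRUE, 40, 40) & (col(lab) <= 40) & TRUE,
                       adipose = matrix(FALSE, 40, 40),
                       stroma = matrix(FALSE, 40, 40),
                       pixel_size_um = 1, dilation_um = 150),
                  class = "region_partition")
  # tumour region = whole tissue here: 600 tumour px, 200 stroma px
  pt$tumour <- lab != 10L
  cm <- composition(pt, lm)
  expect_equal(cm$tumour_stroma_ratio, 600 / 200)
  expect_equal(cm$til_pct, 0)
  # half the stromal compartment lymphocytes -> TIL 50%
  lab2 <- lab; lab2[1:10, 31:40] <- 6L
  cm2 <- composition(pt, label_map(lab2, 1))
  expect_equal(cm2$til_pct, 50)
  # all tumour: TSR missing
  lab3 <- lab; lab3[lab3 == 9L] <- 3L
  cm3 <- composition(pt, label_map(lab3, 1))
  expect_true(is.na(cm3$tumour_stroma_ratio))
})

test_that("group comparisons: nulls, shifts, and the BH step-up rule", {
  set.seed(101)
  # identical groups: p ~ 1
  df <- data.frame(v = rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 2),
                   g = rep(c("a", "b"), each = 5))
  out <- compare_groups(df, v, g)
  expect_gt(out$p_value, 0.99)
  # a 3-sigma shift at n = 20 is detected
  df2 <- data.frame(v = c(rnorm(20), rnorm(20, 3)),
                    g = rep(c("a", "b"), each = 20))
  expect_lt(compare_groups(df2, v, g)$p_value, 1e-3)
  # BH on p = {0.01, 0.02, 0.03, 0.04} adjusts all to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # paired mode on consecutive ring levels
  df3 <- data.frame(subject = rep(1:6, times = 3),
                    ring = rep(1:3, each = 6),
                    v = rnorm(18))
  out3 <- compare_groups(df3, v, ring, subject = subject, paired = TRUE)
  expect_equal(nrow(out3), 2)
  expect_equal(out3$n1, c(6, 6))
  # insufficient observations give missing with a warning
  df4 <- data.frame(v = c(1, 2, 3), g = c("a", "a", "b"))
  expect_warning(out4 <- compare_groups(df4, v, g), "insufficient")
  expect_true(is.na(out4$p_value))
})

test_that("parameter correlations: identity, negation, independence", {
  set.seed(55)
  x <- rnorm(30)
  out <- correlate_parameters(data.frame(a = x), data.frame(a = x))
  expect_equal(out$r, 1)
  out2 <- correlate_parameters(data.frame(a = x), data.frame(a = -x))
  expect_equal(out2$r, -1)
  out3 <- correlate_parameters(data.frame(a = rnorm(100)),
                               data.frame(a = rnorm(100)))
  expect_lt(abs(out3$r), 0.3)
  # zero variance is missing
  out4 <- correlate_parameters(data.frame(a = rep(1, 10)),
                               data.frame(a = rnorm(10)))
  expect_true(is.na(out4$r))
})

test_that("a uniform marker yields a flat ring profile", {
  set.seed(77)
  # one subject cohort: uniform Bernoulli lymphocyte marking of the stroma
  prof <- purrr::map(1:8, function(s) {
    lab <- matrix(9L, 160, 160)
    g <- expand.grid(1:160, 1:160)
    tum <- matrix((g[, 1] - 80)^2 + (g[, 2] - 80)^2 <= 30^2, 160, 160)
    lab[tum] <- 3L
    mark <- matrix(runif(160 * 160) < 0.1, 160, 160) & !tum
    lab[mark] <- 6L
    lm <- label_map(lab, 2)
    rs <- distance_rings(tum, lm, ring_width_um = 25, n_rings = 5)
    dplyr::mutate(lymphocytes_by_distance(rs, lm), subject = s)
  }) |> purrr::list_rbind()
  out <- compare_groups(prof, lymphocyte_pct, ring, subject = subject,
                        paired = TRUE, adjust = TRUE)
  expect_true(all(out$p_adjusted >= 0.05))
})
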