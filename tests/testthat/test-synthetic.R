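test_that("scenes are bit-identical under the same seed", {
  cfg <- synth_config(seed = 42, canvas_px = 96)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$label_map$labels, b$label_map$labels)
  expect_identical(a$instances, b$instances)
})

test_that("a request for no structures yields an all-stroma map", {
  cfg <- synth_config(seed = 1, canvas_px = 64, n_vessels = 0, n_tumour = 0,
                      n_benign = 0, n_adipose = 0, n_lymphocyte = 0,
                      n_nerve = 0, n_muscle = 0, n_leukocyte = 0,
                      background_band = FALSE)
  sc <- generate_scene(cfg)
  expect_true(all(sc$label_map$labels == class_code("STROMA")))
  expect_equal(nrow(sc$instances), 0)
})

test_that("vessel truth is the filled shape while the rendering is an annulus", {
  cfg <- synth_config(seed = 3, canvas_px = 128, n_vessels = 1, n_tumour = 0,
                      n_benign = 0, n_adipose = 0, n_lymphocyte = 0,
                      n_nerve = 0, n_muscle = 0, n_leukocyte = 0,
                      vessel_outer_radius_px = c(20, 20),
                      vessel_elongation = c(1, 1), vessel_wall_px = c(4, 4),
                      vessel_gap_prob = 0, background_band = FALSE,
                      blur_sigma = 0, noise_sd = 0)
  sc <- generate_scene(cfg)
  ins <- sc$instances
  vmask <- sc$label_map$labels == 1L
  # truth component equals the full drawn disk (wall + lumen)
  expect_equal(sum(vmask), ins$area_px)
  expect_equal(ins$area_px, sum(vmask), tolerance = 0)
  expect_gt(ins$area_px, pi * 19^2)
  # the lumen is rendered unstained (near-white), the wall DAB-brown:
  # red channel high in both, blue much lower in the wall
  ctr <- round(c(ins$centre_row, ins$centre_col))
  expect_gt(sc$rgb[ctr[1], ctr[2], 3], 0.8)          # lumen blue channel high
  wall_px <- which(vmask & !is.na(vmask))
  # sample a wall pixel: on the outer ring at angle 0
  wr <- ctr[1]; wc <- ctr[2] + 18
  expect_lt(sc$rgb[wr, wc, 3], 0.5)                  # wall blue channel low
  expect_gt(sc$rgb[wr, wc, 1], sc$rgb[wr, wc, 3])    # warm brown
})

test_that("ground-truth instances equal connected components for separated vessels", {
  for (seed in c(2, 9, 33)) {
    sc <- generate_scene(synth_config(seed = seed, canvas_px = 256, n_vessels = 6))
    comp <- label_vessels(sc$label_map, min_area_px = 1)
    expect_equal(nrow(comp), nrow(sc$instances))
  }
})

test_that("morphometry on ground truth recovers the drawn parameters", {
  # elongated ellipses: measured axis ratio within 5% of the drawn one
  errs <- c()
  for (s in 1:4) {
    cfg <- synth_config(seed = s, canvas_px = 320, n_vessels = 3, n_tumour = 0,
                        n_benign = 0, n_adipose = 0, n_lymphocyte = 0,
                        n_nerve = 0, n_muscle = 0, n_leukocyte = 0,
                        vessel_outer_radius_px = c(28, 40),
                        vessel_elongation = c(1.5, 2.5),
                        background_band = FALSE)
    sc <- generate_scene(cfg)
    mv <- measure_vessels(sc$label_map)
    ins <- sc$instances
    for (i in seq_len(nrow(ins))) {
      j <- which.min((mv$centroid_row - ins$centre_row[i])^2 +
                       (mv$centroid_col - ins$centre_col[i])^2)
      errs <- c(errs, abs(mv$axis_ratio[j] - ins$axis_ratio[i]) / ins$axis_ratio[i])
    }
  }
  expect_lt(max(errs), 0.05)

  # strips: twice the mean inscribed-disk radius recovers the drawn width
  cfg <- synth_config(seed = 5, canvas_px = 256, n_vessels = 3, n_tumour = 0,
                      n_benign = 0, n_adipose = 0, n_lymphocyte = 0,
                      n_nerve = 0, n_muscle = 0, n_leukocyte = 0,
                      vessel_outer_radius_px = c(24, 32),
                      vessel_elongation = c(2.5, 3.5),
                      vessel_shape = "strip", background_band = FALSE)
  sc <- generate_scene(cfg)
  mv <- measure_vessels(sc$label_map)
  ins <- sc$instances
  for (i in seq_len(nrow(ins))) {
    j <- which.min((mv$centroid_row - ins$centre_row[i])^2 +
                     (mv$centroid_col - ins$centre_col[i])^2)
    width_meas <- 2 * mv$thickness_um[j] / sc$label_map$pixel_size_um
    expect_lt(abs(width_meas - ins$width_px[i]), 1)
  }
})

test_that("datasets land on disk with manifest and one-hot masks", {
  dir <- withr::local_tempdir()
  cfg <- toy_tile_config(500)
  suppressMessages(generate_dataset(cfg, 4, dir))
  expect_length(list.files(dir, pattern = "img_"), 4)
  expect_length(list.files(dir, pattern = "lab_"), 4)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$n_tiles, 4)
  # tiles read back through the package conventions
  lm <- read_label_map(file.path(dir, "lab_001.png"), cfg$pixel_size_um)
  expect_true(all(lm$labels %in% 1:10))
  oh <- one_hot(lm)
  expect_true(all(apply(oh, c(1, 2), sum) == 1))
  # every requested class appears somewhere in the set
  pooled <- Reduce(`+`, lapply(1:4, function(i) {
    tabulate(read_label_map(file.path(dir, sprintf("lab_%03d.png", i)))$labels, 10)
  }))
  requested <- c(1, 3, 4, 5, 6, 7, 9, 10)  # classes with positive counts + base
  expect_true(all(pooled[requested] > 0))
})

test_that("impossible placements raise an error rather than truncate", {
  cfg <- synth_config(seed = 1, canvas_px = 32, n_vessels = 30,
                      vessel_outer_radius_px = c(10, 14))
  expect_error(generate_scene(cfg), "canvas too small")
})
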