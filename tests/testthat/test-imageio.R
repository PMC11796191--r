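test_that("image round trips through PNG with explicit pixel size", {
  img <- array(runif(32 * 24 * 3), c(32, 24, 3))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  got <- read_image(path, pixel_size_um = 0.5034)
  expect_equal(got$height_px, 32)
  expect_equal(got$width_px, 24)
  expect_equal(got$pixel_size_um, 0.5034)
  expect_equal(dim(got$image), c(32, 24, 3))
  expect_equal(got$image, img, tolerance = 1 / 255)
})

test_that("TIFF resolution metadata yields the pixel size", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  path <- withr::local_tempfile(fileext = ".tiff")
  # 2 um pixels = 5000 px/cm
  tiff::writeTIFF(img, path, compression = "none")
  expect_error(read_image(path), "pixel size")
  got <- read_image(path, pixel_size_um = 2)
  expect_equal(got$pixel_size_um, 2)
})

test_that("missing files and formats raise explicit errors", {
  expect_error(read_image("does-not-exist.png"), "not found")
  path <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", path)
  expect_error(read_image(path, 1), "unreadable format")
})

test_that("label maps round trip through grayscale PNG", {
  lab <- matrix(sample(1:10, 300, TRUE), 20)
  lm <- label_map(lab, 0.5034)
  path <- withr::local_tempfile(fileext = ".png")
  write_label_map(lm, path)
  back <- read_label_map(path, 0.5034)
  expect_identical(back$labels, lm$labels)
})

test_that("annotations rasterize with precedence and stroma remainder", {
  # single vessel polygon: polygon pixels become VESSEL, remainder STROMA
  ann <- tibble::tibble(class = "VESSEL", code = 1L,
                        rings = list(list(cbind(x = c(2, 12, 12, 2),
                                                y = c(2, 2, 12, 12)))))
  lm <- rasterize_annotations(ann, 20, 20, 1)
  expect_gt(sum(lm$labels == 1L), 0)
  expect_true(all(lm$labels %in% c(1L, 9L)))

  # overlapping VESSEL and MUSCLE: overlap resolved by precedence on a toy
  ann2 <- tibble::tibble(
    class = c("MUSCLE", "VESSEL"), code = c(2L, 1L),
    rings = list(list(cbind(x = c(0, 9, 9, 0), y = c(0, 0, 9, 9))),
                 list(cbind(x = c(3, 6, 6, 3), y = c(3, 3, 6, 6)))))
  lm2 <- rasterize_annotations(ann2, 10, 10, 1)
  # every pixel inside the vessel square is VESSEL, muscle elsewhere in its square
  expect_true(all(lm2$labels[4:6, 4:6] == 1L))
  expect_true(all(lm2$labels[1:3, 1:9] == 2L))

  # empty annotation set: all stroma
  lm3 <- rasterize_annotations(NULL, 8, 8, 1)
  expect_true(all(lm3$labels == 9L))
})

test_that("GeoJSON annotations are read with class names and holes", {
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(classification = list(name = "Vessel")),
    geometry = list(type = "Polygon",
                    coordinates = list(
                      list(list(1, 1), list(15, 1), list(15, 15), list(1, 15)),
                      list(list(5, 5), list(10, 5), list(10, 10), list(5, 10)))))))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  ann <- read_annotations(path)
  expect_equal(ann$class, "VESSEL")
  expect_length(ann$rings[[1]], 2)
  lm <- rasterize_annotations(ann, 20, 20, 1)
  expect_equal(unname(lm$labels[8, 8]), 9L)  # hole stays open (even-odd rule)
  expect_equal(unname(lm$labels[3, 3]), 1L)

  bad <- gj
  bad$features[[1]]$properties$classification$name <- "NOPE"
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_annotations(path), "unknown tissue class")
})

test_that("tiling covers the image, pads with mirror, and masks are one-hot", {
  lab <- matrix(sample(1:10, 1024 * 1024, TRUE), 1024)
  img <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  tl <- extract_tiles(img, label_map(lab, 1), 512, 512)
  expect_equal(nrow(tl), 4)

  lab2 <- lab[1:600, 1:600]
  tl2 <- extract_tiles(img[1:600, 1:600, ], label_map(lab2, 1), 512, 512)
  expect_equal(nrow(tl2), 4)
  # mirror padding: the padded margin reflects the interior
  m <- tl2$labels[[4]]
  expect_equal(m[1:88, 1:88], lab2[513:600, 513:600])
  expect_equal(m[89, 1:88], lab2[599, 513:600])  # first mirrored row

  for (i in seq_len(nrow(tl2))) {
    sums <- apply(tl2$mask[[i]], c(1, 2), sum)
    expect_true(all(sums == 1))
  }
  expect_error(extract_tiles(img, label_map(lab, 1), 0), "positive")
})

test_that("tiling conserves per-class pixel counts inside exact coverage", {
  lab <- matrix(sample(1:10, 256 * 256, TRUE), 256)
  img <- array(0.5, c(256, 256, 3))
  tl <- extract_tiles(img, label_map(lab, 1), 128, 128)
  pooled <- Reduce(`+`, lapply(tl$labels, function(x) tabulate(x, 10)))
  expect_equal(pooled, tabulate(lab, 10))
})

test_that("measurement tables round trip through CSV", {
  df <- tibble::tibble(vessel_id = 1:3, area_um2 = c(10.5, 20.25, 31.125),
                       circularity = c(0.9, 0.8, 0.7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(df, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(df))
  empty <- df[0, ]
  write_measurements(empty, path)
  expect_equal(nrow(read_measurements(path)), 0)
})

test_that("pixel areas convert to square microns for arbitrary sizes", {
  for (ps in c(0.25, 0.5034, 1, 2.2)) {
    n <- sample.int(1000, 1)
    expect_equal(measure_area(n, ps), n * ps^2)
  }
  # the 40 px minimum vessel converts to ~10 um^2 at the acquisition pixel
  expect_equal(round(measure_area(40, 0.5034)), 10)
})
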