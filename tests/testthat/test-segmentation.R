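test_that("a uniform bright image is entirely adipocyte at any interior threshold", {
  img <- raster_image(matrix(255, 64, 64), bit_depth = 8L, um_per_px = 1)
  for (thr in c(1, 128, 254)) {
    mask <- binarize(img, threshold = thr)
    expect_true(all(mask$adipocyte))
  }
  ai <- compute_adipocyte_index(binarize(img, 128), force = TRUE)
  expect_identical(ai$value, 1)
  expect_identical(ai$image_area_um2, 64 * 64 * 1)
})

test_that("the 16-bit default threshold classes only near-black pixels as matrix", {
  # light-is-high file values: 0 (pure black), 5 (near black), 9, 5000, 65535
  px <- matrix(c(0, 5, 9, 5000, 65535, 65535), 2, 3)
  img <- raster_image(px, bit_depth = 16L, um_per_px = 1)
  mask <- binarize(img)  # default 65,527 on the dark-is-high scale
  expect_identical(mask$provenance$threshold_dark_high, 65527)
  # dark value = 65535 - light value; intervacuolar iff dark >= 65527,
  # i.e. light value <= 8
  expect_identical(as.vector(!mask$adipocyte),
                   as.vector(px <= 8))
})

test_that("thresholds outside the intensity range are refused", {
  img <- raster_image(matrix(10, 4, 4), bit_depth = 8L, um_per_px = 1)
  expect_error(binarize(img, threshold = 300), "outside")
  expect_error(binarize(img, threshold = -1), "outside")
})

test_that("binarize is idempotent in effect on a rendered mask", {
  res <- generate_tissue_image(
    tissue_spec(width_px = 128L, height_px = 128L, um_per_px = 1,
                radius_log_mean = log(8), target_fraction = 0.4,
                noise_sd = 0, speck_rate = 0, seed = 31))
  m1 <- binarize(res$image, 128)
  m2 <- binarize(mask_to_image(m1$adipocyte), 128)
  expect_identical(m1$adipocyte, m2$adipocyte)
})

test_that("raising the threshold toward the dark extreme never grows the matrix phase", {
  set.seed(32)
  img <- raster_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64),
                      bit_depth = 8L, um_per_px = 1)
  counts <- vapply(seq(0, 255, by = 15), function(thr) {
    sum(!binarize(img, thr)$adipocyte)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("separated discs get distinct labels; clipped discs are filtered out", {
  m <- matrix(FALSE, 64, 64)
  m <- draw_disc(m, 20, 20, 8)
  m <- draw_disc(m, 45, 40, 8)
  m <- draw_disc(m, 63, 60, 8)  # clipped by the border
  lab <- label_adipocytes(make_mask(m))
  expect_identical(max(lab), 3L)
  labf <- filter_complete_cells(lab, speck_floor_px = 5)
  expect_identical(length(setdiff(unique(as.vector(labf)), 0L)), 2L)
  expect_identical(attr(labf, "n_removed_border"), 1L)
})

test_that("diagonally touching pixels join one component", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE
  lab <- label_adipocytes(make_mask(m))
  expect_identical(max(lab), 1L)
})

test_that("watershed de-clustering splits merged cells only when asked", {
  m <- matrix(FALSE, 60, 100)
  m <- draw_disc(m, 35, 30, 18)
  m <- draw_disc(m, 65, 30, 18)  # overlaps the first
  mask <- make_mask(m)
  expect_identical(max(label_adipocytes(mask, split = FALSE)), 1L)
  lab <- label_adipocytes(mask, split = TRUE)
  expect_identical(max(lab), 2L)
  # each known centre falls in a different label
  expect_false(lab[30, 35] == lab[30, 65])
})

test_that("labels below the speck floor are discarded as debris", {
  m <- matrix(FALSE, 40, 40)
  m <- draw_disc(m, 15, 15, 6)
  m[30, 30] <- m[30, 31] <- TRUE  # 2 px speck
  lab <- label_adipocytes(make_mask(m))
  labf <- filter_complete_cells(lab, speck_floor_px = 20)
  expect_identical(length(setdiff(unique(as.vector(labf)), 0L)), 1L)
  expect_identical(attr(labf, "n_removed_speck"), 1L)
})

test_that("cell measurement follows the circular model closed form", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 6:15] <- TRUE  # 100 px interior square
  lab <- label_adipocytes(make_mask(m))
  meas <- measure_cells(lab, um_per_px = 1)
  expect_identical(meas$cells$pixel_count, 100L)
  expect_equal(meas$cells$equivalent_diameter_um, 11.2838, tolerance = 1e-4)
  expect_equal(meas$cells$area_um2, 100)
  expect_identical(meas$n_complete_cells, 1L)
})

test_that("a rasterized disc's measured area is within one perimeter band of truth", {
  m <- matrix(FALSE, 60, 60)
  m <- draw_disc(m, 30, 30, 20)  # radius 20 um at 1 um/px
  meas <- measure_cells(label_adipocytes(make_mask(m)), um_per_px = 1)
  expect_lt(abs(meas$cells$area_um2 - pi * 400), 2 * pi * 20 * 1)
})

test_that("areas are calibration-covariant and the AI is calibration-invariant", {
  res <- generate_tissue_image(
    tissue_spec(width_px = 128L, height_px = 128L, um_per_px = 1,
                radius_log_mean = log(8), target_fraction = 0.4,
                noise_sd = 0, speck_rate = 0, seed = 33))
  mask1 <- binarize(res$image, 128)
  lab <- label_adipocytes(mask1)
  m1 <- measure_cells(lab, um_per_px = 1)
  m2 <- measure_cells(lab, um_per_px = 2)
  expect_equal(m2$cells$area_um2, 4 * m1$cells$area_um2)
  img2 <- res$image
  img2$um_per_px <- 2
  ai1 <- compute_adipocyte_index(mask1, force = TRUE)
  ai2 <- compute_adipocyte_index(binarize(img2, 128), force = TRUE)
  expect_identical(ai1$value, ai2$value)
})

test_that("mean area is recovered within 3% on noise-free synthetic packings", {
  for (seed in c(41, 42)) {
    res <- generate_tissue_image(
      tissue_spec(seed = seed, noise_sd = 0, speck_rate = 0))
    truth <- res$truth
    lm_ <- truth$label_mask
    border <- unique(c(lm_[1, ], lm_[nrow(lm_), ], lm_[, 1], lm_[, ncol(lm_)]))
    true_mean <- mean(truth$cell_areas_um2[
      setdiff(seq_along(truth$cell_areas_um2), border)])
    seg <- segment_image(res$image, threshold = 128, min_cells = 50)
    expect_lt(abs(seg$measurements$mean_area_um2 - true_mean) / true_mean,
              0.03)
    expect_true(seg$qc_pass)
  }
})

test_that("the sample mean refuses to report on fewer than the minimum cells", {
  m <- matrix(FALSE, 40, 40)
  m <- draw_disc(m, 20, 20, 8)
  meas <- measure_cells(label_adipocytes(make_mask(m)), um_per_px = 1)
  err <- tryCatch(mean_adipocyte_area(meas, min_cells = 100),
                  error = function(e) e)
  expect_s3_class(err, "adipo_insufficient_cells")
  expect_identical(err$observed, 1L)
  expect_equal(mean_adipocyte_area(meas, min_cells = 1),
               meas$mean_area_um2)
})

test_that("an all-border field yields no complete cells and trips the minimum check", {
  m <- matrix(TRUE, 30, 30)  # one blob touching every border
  labf <- filter_complete_cells(label_adipocytes(make_mask(m)))
  meas <- measure_cells(labf, um_per_px = 1)
  expect_identical(meas$n_complete_cells, 0L)
  expect_error(mean_adipocyte_area(meas), class = "adipo_insufficient_cells")
})
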