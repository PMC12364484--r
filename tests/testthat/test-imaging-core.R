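test_that("um_to_px rounds half-up with a one-pixel floor", {
  expect_identical(um_to_px(1.0, 0.09), 11L)   # the 1 um band at 90 nm pixels
  expect_identical(um_to_px(0.09, 0.09), 1L)
  expect_identical(um_to_px(0.01, 0.09), 1L)   # floor at 1 px
  expect_identical(um_to_px(0.135, 0.09), 2L)  # exact half rounds up
  expect_error(um_to_px(-1, 0.09), "positive")
  expect_error(um_to_px(1, 0), "positive")
})

test_that("domain containers enforce their invariants", {
  expect_error(calibrated_image(matrix(1, 1, 5), 0.09), "2 rows")
  expect_error(calibrated_image(matrix(-1, 4, 4), 0.09), "non-negative")
  expect_error(calibrated_image(matrix(Inf, 4, 4), 0.09), "finite")
  expect_error(calibrated_image(matrix(1, 4, 4), -0.09), "positive")

  m <- binary_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2), 0.5)
  expect_equal(mask_area_um2(m), 3 * 0.25)

  lm0 <- label_map(matrix(c(0L, 5L, 5L, 9L), 2), 0.09)
  expect_identical(sort(unique(as.vector(lm0$pixels))), c(0L, 1L, 2L))
  expect_identical(n_cells(lm0), 2L)
  expect_error(label_map(matrix(-1L, 2, 2), 0.09), "non-negative")
})

test_that("write_image / read_image round-trips pixels and calibration", {
  img <- calibrated_image(matrix(sample(0:65535, 48 * 48, TRUE), 48),
                          pixel_size_um = 0.09, channel = "HABP")
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  back <- read_image(path)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$pixel_size_um, 0.09)
  expect_identical(back$channel, "HABP")

  # explicit override takes precedence over the stored calibration
  over <- read_image(path, pixel_size_um = 0.2)
  expect_equal(over$pixel_size_um, 0.2)
})

test_that("read_image refuses files with no resolvable pixel size", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4), path, bits.per.sample = 16L)
  expect_error(read_image(path), "pixel size unknown")
  expect_equal(read_image(path, pixel_size_um = 0.09)$pixel_size_um, 0.09)
  expect_error(read_image(file.path(tempdir(), "nope.tif")), "not found")
})

test_that("write_results is sorted, deterministic and validates input", {
  rows <- dplyr::bind_rows(
    field_result("f2", "mcao", "striatum", "b_metric", 2),
    field_result("f1", "sham", "cortex", "fractal_dimension", 1.52),
    field_result("f1", "sham", "cortex", "a_metric", 0.5)
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_results(rows, p1)
  write_results(rows[sample.int(nrow(rows)), ], p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  out <- readr::read_csv(p1, show_col_types = FALSE)
  expect_identical(names(out), c("field", "condition", "region",
                                 "metric", "value", "units"))
  expect_identical(out$field, c("f1", "f1", "f2"))
  expect_error(write_results(rows[0, ], p1), "no results")
  expect_error(write_results(dplyr::select(rows, -value), p1), "missing column")
})

test_that("micrometre outputs scale with the calibration at fixed pixels", {
  px <- matrix(FALSE, 30, 120)
  px[15, 10:110] <- TRUE
  sk1 <- summarize_skeletons(binary_mask(px, 0.09))
  sk2 <- summarize_skeletons(binary_mask(px, 0.18))
  expect_equal(sk2$lsp_um, 2 * sk1$lsp_um)
  expect_equal(mask_area_um2(binary_mask(px, 0.18)),
               4 * mask_area_um2(binary_mask(px, 0.09)))
})
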