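test_that("uniform images give flat, fully normalized profiles", {
  img <- calibrated_image(matrix(40, 128, 128), 1, "GFAP")
  pr <- radial_profile(img, center = c(64.5, 64.5), bin_um = 8)
  ok <- !is.na(pr$mean_intensity)
  expect_true(all(abs(pr$mean_intensity[ok] - 40) < 1e-9))
  expect_true(all(abs(pr$norm_intensity[ok] - 1) < 1e-9))
})

test_that("a scar annulus peaks at its own bin", {
  sc <- make_lesion_scene(100, 140, 160,
                          channel_profiles = list(Thbs4 = "scar"),
                          image_size = 512, pixel_size_um = 0.9, seed = 8)
  pr <- radial_profile(sc$channels$Thbs4,
                       center = c(sc$truth$lesion$center_row,
                                  sc$truth$lesion$center_col),
                       bin_um = 10)
  expect_true(scar_peak(pr) %in% c(145, 155))
})

test_that("a decreasing radial gradient yields decreasing bin means", {
  n <- 201
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  d <- sqrt((rr - 101)^2 + (cc - 101)^2)
  img <- calibrated_image(pmax(200 - d, 0), 1, "HABP")
  pr <- radial_profile(img, center = c(101, 101), bin_um = 10,
                       max_radius_um = 90)
  expect_true(all(diff(pr$mean_intensity) < 0))
})

test_that("peak ties resolve to the smallest radius", {
  prof <- tibble::tibble(channel = "x", radius_um = c(50, 100, 150, 200),
                         mean_intensity = c(1, 5, 2, 5),
                         norm_intensity = c(0.2, 1, 0.4, 1))
  class(prof) <- c("radial_profile", class(prof))
  expect_equal(scar_peak(prof), 100)
})

test_that("marker ordering from core to penumbra is reproduced", {
  sc <- make_lesion_scene(
    100, 140, 160,
    channel_profiles = list(GFAP = c("core", "scar"), Thbs4 = "scar",
                            Nestin = "scar"),
    image_size = 512, pixel_size_um = 0.9, seed = 12
  )
  ctr <- c(sc$truth$lesion$center_row, sc$truth$lesion$center_col)
  peaks <- vapply(sc$channels, function(ch) {
    scar_peak(radial_profile(ch, center = ctr, bin_um = 10))
  }, numeric(1))
  expect_gte(peaks[["Thbs4"]], peaks[["GFAP"]])
  # scar-only markers peak within one bin of the annulus midpoint
  expect_lte(abs(peaks[["Thbs4"]] - 150), 10)
  expect_lte(abs(peaks[["Nestin"]] - 150), 10)
})

test_that("profiles are invariant under 90-degree rotation about the centre", {
  sc <- make_lesion_scene(60, 90, 110,
                          channel_profiles = list(Thbs4 = "scar"),
                          image_size = 256, pixel_size_um = 1,
                          noise_sd = 10, seed = 3)
  px <- sc$channels$Thbs4$pixels
  ctr <- c(128.5, 128.5)
  p1 <- radial_profile(calibrated_image(px, 1, "T"), ctr, bin_um = 10)
  p2 <- radial_profile(calibrated_image(rot90(px), 1, "T"), ctr, bin_um = 10)
  expect_equal(p1$mean_intensity, p2$mean_intensity, tolerance = 1e-12)
})

test_that("line profiles track a gradient along the sampled segment", {
  n <- 201
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- calibrated_image(cc, 1, "GFAP")
  pr <- line_profile(img, from = c(101, 1), to = c(101, 201), bin_um = 20)
  expect_true(all(diff(pr$mean_intensity) > 0))
  expect_equal(max(pr$norm_intensity, na.rm = TRUE), 1)
})

test_that("profile inputs are validated and empty bins are kept as NA", {
  img <- calibrated_image(matrix(1:100, 10), 1)
  expect_error(radial_profile(img, center = c(50, 5)), "inside the image")
  expect_error(radial_profile(img, center = c(5, 5), bin_um = 0), "positive")
  pr <- radial_profile(img, center = c(5, 5), bin_um = 1, max_radius_um = 20)
  expect_true(any(is.na(pr$mean_intensity))) # bins beyond the corners persist
  empty <- radial_profile(img, center = c(5, 5), bin_um = 1,
                          sector = c(3.13, 3.14), max_radius_um = 3)
  expect_error(scar_peak(empty), "no non-missing bins")
})
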