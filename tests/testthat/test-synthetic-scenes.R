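test_that("straight fibers carry exact polyline arc length as truth", {
  sc <- make_fiber_scene(1, length_um = 18, n_bends = 0, image_size = 256,
                         pixel_size_um = 0.09, seed = 11)
  expect_equal(sc$truth$fibers$length_um, 18)
  v <- sc$truth$fibers$vertices[[1]]
  expect_equal(sqrt(sum((v[2, ] - v[1, ])^2)) * 0.09, 18)
})

test_that("scenes are bit-identical under the same seed", {
  a <- make_fiber_scene(20, length_um = 8, length_sd_um = 1, noise_sd = 5,
                        image_size = 512, seed = 7)
  b <- make_fiber_scene(20, length_um = 8, length_sd_um = 1, noise_sd = 5,
                        image_size = 512, seed = 7)
  expect_identical(a$channels$HABP$pixels, b$channels$HABP$pixels)
  expect_identical(a$truth, b$truth)
  c1 <- make_lesion_scene(100, 140, 160, image_size = 256, pixel_size_um = 2,
                          noise_sd = 3, seed = 5)
  c2 <- make_lesion_scene(100, 140, 160, image_size = 256, pixel_size_um = 2,
                          noise_sd = 3, seed = 5)
  expect_identical(c1$channels$Thbs4$pixels, c2$channels$Thbs4$pixels)
})

test_that("impossible fiber packings fail with a placement error", {
  expect_error(
    make_fiber_scene(10000, length_um = 5, image_size = 64, max_tries = 5),
    "could not place"
  )
})

test_that("noise-free fibers have signal wherever the truth says", {
  sc <- make_fiber_scene(15, length_um = 9, image_size = 512, seed = 3)
  px <- sc$channels$HABP$pixels
  for (v in sc$truth$fibers$vertices) {
    idx <- cbind(pmin(pmax(round(v[, 1]), 1), nrow(px)),
                 pmin(pmax(round(v[, 2]), 1), ncol(px)))
    expect_true(all(px[idx] > 0))
  }
})

test_that("analytic fractal patterns have their constructed pixel counts", {
  line <- make_fractal_pattern("line", size = 243)
  expect_equal(sum(line$pixels), 243)
  expect_equal(max(rowSums(line$pixels)), 243) # single one-pixel-wide row

  sq <- make_fractal_pattern("filled_square", size = 64)
  expect_true(all(sq$pixels))

  carpet <- make_fractal_pattern("sierpinski_carpet", order = 5, size = 243)
  expect_equal(sum(carpet$pixels), 8^5)
  expect_error(make_fractal_pattern("sierpinski_carpet", order = 2, size = 100),
               "3\\^order")
})

test_that("cell scenes seed exact CD44 and spot bookkeeping", {
  sc <- make_cell_scene(4, cd44_positive_fraction = 0.5, image_size = 768,
                        seed = 9)
  expect_equal(sum(sc$truth$cells$cd44_positive), 2L)

  sc2 <- make_cell_scene(3, n_intra_spots = 5, image_size = 768, seed = 10)
  habp_spots <- dplyr::filter(sc2$truth$spots, channel == "HABP",
                              compartment == "intracellular")
  expect_equal(nrow(habp_spots), 15L)
})

test_that("membrane rings hug the cell perimeter", {
  sc <- make_cell_scene(3, membrane_signal = TRUE, image_size = 768, seed = 4)
  px <- sc$channels$HABP$pixels
  on <- which(px > 0, arr.ind = TRUE)
  cells <- sc$truth$cells
  d_to_boundary <- apply(on, 1, function(p) {
    min(abs(sqrt((p[1] - cells$row)^2 + (p[2] - cells$col)^2) -
              cells$radius_px))
  })
  expect_true(all(d_to_boundary <= 1))
})

test_that("lesion scenes validate radii and confine channel mass", {
  expect_error(make_lesion_scene(200, 150, 300), "core < scar inner")
  expect_error(make_lesion_scene(100, 140, 300, image_size = 256,
                                 pixel_size_um = 2),
               "half the image extent")

  sc <- make_lesion_scene(100, 140, 160,
                          channel_profiles = list(Thbs4 = "scar"),
                          image_size = 512, pixel_size_um = 0.9, seed = 2)
  px <- sc$channels$Thbs4$pixels
  ctr <- c(sc$truth$lesion$center_row, sc$truth$lesion$center_col)
  rr <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
  cc <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
  dist_um <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) * 0.9
  in_scar <- dist_um >= 140 & dist_um <= 160
  expect_gte(sum(px[in_scar]) / sum(px), 0.95)
})
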