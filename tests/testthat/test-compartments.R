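test_that("the three compartments partition every field exactly", {
  sc <- make_cell_scene(5, image_size = 768, seed = 31)
  cells <- segment_cells(sc$channels$Thbs4)
  comp <- compartmentalize(cells, band_width_um = 1)
  areas <- compartment_areas(comp)
  expect_equal(sum(areas$n_px), 768L * 768L)
  expect_identical(sort(unique(as.vector(comp$code))), c(1L, 2L, 3L))
  expect_error(compartmentalize(label_map(matrix(0L, 10, 10), 0.09)),
               "empty label map")
  expect_error(compartmentalize(cells, band_width_um = -1), "positive")
})

test_that("the 1 um band around a disk matches the analytic annulus", {
  lm50 <- disk_label_map(50, 200, pixel_size_um = 0.09)
  comp <- compartmentalize(lm50, band_width_um = 1)
  expect_identical(comp$band_px, 11L)
  band_area <- sum(comp$code == 2L)
  expect_lt(abs(band_area - 4 * pi * 50 * 11) / (4 * pi * 50 * 11), 0.05)

  # brute-force oracle: per-pixel Euclidean distance to the boundary pixels
  inside <- lm50$pixels > 0
  boundary <- inside & !(haquant:::shift_mat(inside, 1, 0, FALSE) &
                           haquant:::shift_mat(inside, -1, 0, FALSE) &
                           haquant:::shift_mat(inside, 0, 1, FALSE) &
                           haquant:::shift_mat(inside, 0, -1, FALSE))
  bpix <- which(boundary, arr.ind = TRUE)
  all_pix <- which(matrix(TRUE, 200, 200), arr.ind = TRUE)
  dmin <- apply(all_pix, 1, function(p) {
    sqrt(min((p[1] - bpix[, 1])^2 + (p[2] - bpix[, 2])^2))
  })
  oracle_area <- sum(dmin <= 11)
  expect_lt(abs(band_area - oracle_area) / oracle_area, 0.05)
})

test_that("band variants and ownership behave locally per cell", {
  lmap <- label_map({
    m <- matrix(0L, 300, 300)
    rr <- matrix(1:300, 300, 300); cc <- t(rr)
    m[sqrt((rr - 70)^2 + (cc - 70)^2) <= 25] <- 1L
    m[sqrt((rr - 230)^2 + (cc - 230)^2) <= 25] <- 2L
    m
  }, 0.09)
  comp <- compartmentalize(lmap, band_width_um = 1)
  for (i in 1:2) {
    band_i <- comp$code == 2L & comp$owner == i
    expect_gt(sum(band_i), 0)
    expect_equal(max(haquant:::label_components_8(band_i)), 1L)
  }
  outer_band <- compartmentalize(lmap, 1, band_side = "outer")
  expect_equal(sum(outer_band$code == 2L & lmap$pixels > 0), 0L)
  inner_band <- compartmentalize(lmap, 1, band_side = "inner")
  expect_equal(sum(inner_band$code == 2L & lmap$pixels == 0), 0L)
})

test_that("membrane rings register as membrane HA, never intracellular", {
  sc <- make_cell_scene(4, membrane_signal = TRUE, image_size = 768, seed = 33)
  cells <- segment_cells(sc$channels$Thbs4)
  comp <- compartmentalize(cells, 1)
  ha <- segment_matrix(sc$channels$HABP)$mask
  rec <- quantify_cells(cells, comp, ha)
  expect_true(all(rec$ha_membrane_um2 > 0))
  expect_true(all(rec$ha_intracellular_um2 == 0))
  expect_true(all(is.na(rec$cd44_internalized)))
})

test_that("seeded spots and CD44 puncta are recovered exactly", {
  sc <- make_cell_scene(6, n_intra_spots = 5, n_extra_spots = 7,
                        cd44_positive_fraction = 0.5, image_size = 1024,
                        seed = 34)
  cells <- segment_cells(sc$channels$Thbs4)
  comp <- compartmentalize(cells, 1)
  ha <- segment_matrix(sc$channels$HABP)$mask
  cd44 <- segment_matrix(sc$channels$CD44)$mask
  rec <- quantify_cells(cells, comp, ha, cd44)
  expect_equal(rec$intracellular_spots, rep(5L, 6))
  # map recovered labels back to generator cells via their centres
  truth <- sc$truth$cells
  lab_at_center <- cells$pixels[cbind(round(truth$row), round(truth$col))]
  expect_identical(rec$cd44_internalized[lab_at_center], truth$cd44_positive)
  expect_equal(internalization_fraction(rec), 0.5)

  # HA-area decomposition identity holds exactly
  total <- mask_area_um2(ha)
  parts <- sum(rec$ha_intracellular_um2) + sum(rec$ha_membrane_um2) +
    field_extracellular_ha(comp, ha)
  expect_equal(parts, total)

  # extracellular spots reappear as extracellular components
  extra <- ha$pixels & comp$code == 3L
  expect_equal(max(haquant:::label_components_8(extra)), 7L)
})

test_that("spot counts survive positive affine intensity rescaling", {
  sc <- make_cell_scene(3, n_intra_spots = 4, image_size = 768, seed = 35)
  cells <- segment_cells(sc$channels$Thbs4)
  comp <- compartmentalize(cells, 1)
  count_spots <- function(img) {
    ha <- segment_matrix(img)$mask
    sum(quantify_cells(cells, comp, ha)$intracellular_spots)
  }
  base <- count_spots(sc$channels$HABP)
  rescaled <- calibrated_image(sc$channels$HABP$pixels * 2.5 + 7, 0.09, "HABP")
  expect_equal(count_spots(rescaled), base)
  expect_equal(base, 12L)
})

test_that("quantification validates shapes and CD44 availability", {
  sc <- make_cell_scene(2, membrane_signal = TRUE, image_size = 768, seed = 36)
  cells <- segment_cells(sc$channels$Thbs4)
  comp <- compartmentalize(cells, 1)
  small <- binary_mask(matrix(FALSE, 10, 10), 0.09)
  expect_error(quantify_cells(cells, comp, small), "mismatch")
  expect_error(field_extracellular_ha(comp, small), "mismatch")
  rec <- quantify_cells(cells, comp, segment_matrix(sc$channels$HABP)$mask)
  expect_error(internalization_fraction(rec), "CD44")
  expect_error(internalization_fraction(rec[0, ]), "no cell records")
})
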