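test_that("thinning reduces bars to centerlines and preserves components", {
  bar <- matrix(FALSE, 20, 220)
  bar[9:11, 10:210] <- TRUE
  sk <- skeletonize(binary_mask(bar, 0.09))
  expect_true(abs(sum(sk$pixels) - 201) <= 4) # up to 2 px lost per tip
  expect_equal(max(haquant:::label_components_8(sk$pixels)), 1L)

  two <- bar
  two[15, 10:100] <- TRUE
  sk2 <- skeletonize(binary_mask(two, 0.09))
  expect_equal(max(haquant:::label_components_8(sk2$pixels)), 2L)

  disk <- matrix(FALSE, 60, 60)
  rr <- matrix(1:60, 60, 60); cc <- t(rr)
  disk[sqrt((rr - 30)^2 + (cc - 30)^2) <= 20] <- TRUE
  skd <- skeletonize(binary_mask(disk, 0.09))
  expect_equal(max(haquant:::label_components_8(skd$pixels)), 1L)
  expect_lt(sum(skd$pixels), sum(disk) / 10)

  expect_error(skeletonize(binary_mask(matrix(FALSE, 5, 5), 0.09)), "empty")
})

test_that("the pixel graph carries calibrated orthogonal/diagonal weights", {
  m <- matrix(FALSE, 5, 5); m[3, 2:4] <- TRUE
  g <- build_graph(binary_mask(m, 0.09))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$edges$weight_um, c(0.09, 0.09))

  d <- matrix(FALSE, 5, 5); d[cbind(2:4, 2:4)] <- TRUE
  gd <- build_graph(binary_mask(d, 0.09))
  expect_equal(nrow(gd$edges), 2L)
  expect_equal(gd$edges$weight_um, rep(0.09 * sqrt(2), 2))

  iso <- matrix(FALSE, 4, 4); iso[2, 2] <- TRUE
  gi <- build_graph(binary_mask(iso, 0.09))
  expect_equal(gi$n_nodes, 1L)
  expect_equal(nrow(gi$edges), 0L)
  expect_equal(longest_shortest_path(gi, 1), 0)
})

test_that("geodesic diameter matches closed forms on forced geometries", {
  straight <- matrix(FALSE, 5, 210); straight[3, 5:205] <- TRUE
  g <- build_graph(binary_mask(straight, 0.09))
  expect_equal(longest_shortest_path(g, 1), 18)

  lshape <- matrix(FALSE, 120, 120)
  lshape[10, 10:110] <- TRUE  # 101 px arm
  lshape[10:110, 10] <- TRUE  # shares the corner pixel
  gl <- build_graph(binary_mask(lshape, 0.09))
  # the diagonal step at the corner shortens two orthogonal steps
  expect_equal(longest_shortest_path(gl, 1), 198 * 0.09 + sqrt(2) * 0.09)

  diagonal <- matrix(FALSE, 120, 120)
  diagonal[cbind(10:110, 10:110)] <- TRUE
  gdg <- build_graph(binary_mask(diagonal, 0.09))
  expect_equal(longest_shortest_path(gdg, 1), 100 * sqrt(2) * 0.09)

  expect_error(longest_shortest_path(g, 99), "unknown component")
})

test_that("endpoint-restricted search equals the all-pairs maximum on trees", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      n <- sample(5:200, 1)
      edges <- random_tree_edges(n)
      g <- skeleton_graph(edges, n_nodes = n, pixel_size_um = 0.09)
      expect_equal(longest_shortest_path(g, 1),
                   fw_max_distance(edges, n), tolerance = 1e-9)
    }
  })
})

test_that("pure loops fall back to the all-pairs geodesic maximum", {
  ring <- matrix(FALSE, 12, 12)
  ring[4, 4:8] <- TRUE; ring[8, 4:8] <- TRUE
  ring[4:8, 4] <- TRUE; ring[4:8, 8] <- TRUE
  g <- build_graph(binary_mask(ring, 1))
  expect_equal(sum(g$degree == 1L), 0L)
  lsp <- longest_shortest_path(g, 1)
  expect_gt(lsp, 0)
  # on a cycle the diameter is at most half the total cycle length
  expect_lte(lsp, sum(g$edges$weight_um) / 2 + 1e-9)
})

test_that("skeleton summaries report topology counts and flag tiny parts", {
  cross <- matrix(FALSE, 120, 120)
  cross[60, 10:110] <- TRUE
  cross[10:110, 60] <- TRUE
  sm <- summarize_skeletons(binary_mask(cross, 0.09))
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$n_endpoints, 4L)
  expect_gte(sm$n_junctions, 1L)
  expect_equal(sm$n_branches, 4L)

  dot <- matrix(FALSE, 5, 5); dot[3, 3] <- TRUE
  sd <- summarize_skeletons(binary_mask(dot, 0.09))
  expect_equal(sd$lsp_um, 0)
  expect_true(sd$small)
})

test_that("geodesic diameter is invariant under rotation and mirror", {
  sc <- make_fiber_scene(8, length_um = 7, image_size = 384, seed = 17)
  skel <- skeletonize(segment_matrix(sc$channels$HABP)$mask)
  lsp_of <- function(px) {
    g <- build_graph(binary_mask(px, 0.09))
    sort(vapply(seq_len(max(g$component)), function(k)
      longest_shortest_path(g, k), numeric(1)))
  }
  base <- lsp_of(skel$pixels)
  expect_equal(lsp_of(rot90(skel$pixels)), base, tolerance = 1e-9)
  expect_equal(lsp_of(skel$pixels[nrow(skel$pixels):1, ]), base,
               tolerance = 1e-9)
})

test_that("ecdf_table counts right-continuous cumulative fractions", {
  tab <- ecdf_table(c(1, 2, 2, 4))
  expect_equal(tab$value, c(1, 2, 4))
  expect_equal(tab$fraction, c(0.25, 0.75, 1))
  expect_equal(ecdf_table(5)$fraction, 1)
  withr::with_seed(1, {
    x <- rnorm(200)
    f <- ecdf_table(x)$fraction
    expect_true(all(diff(f) > 0) && all(f >= 0 & f <= 1))
  })
  expect_error(ecdf_table(numeric(0)), "empty")
})
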