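#' Synthetic micrograph scenes with exact ground truth
#'
#' The generators in this module render micrograph-like multichannel images
#' (HABP matrix fibers, Thbs4 cell bodies, CD44 puncta, ring-shaped lesions)
#' together with the exact geometry used to draw them. The recorded truth is
#' the oracle against which segmentation, skeleton, compartment and profile
#' measurements are validated, replacing the undeposited animal imaging data.
#'
#' A `synthetic_scene` holds a named list of [calibrated_image()] channels
#' (all sharing shape and pixel size), a `truth` list and the generating
#' seed. Identical arguments and seed reproduce bit-identical scenes.
#'
#' @name synthetic_scene
NULL

new_synthetic_scene <- function(channels, truth, pixel_size_um, seed) {
  stopifnot(length(channels) > 0)
  dims <- unique(lapply(channels, function(ch) dim(ch$pixels)))
  if (length(dims) != 1L) stop("scene channels must share one shape", call. = FALSE)
  structure(list(channels = channels, truth = truth,
                 pixel_size_um = pixel_size_um, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$channels[[1]]$pixels)
  cat(sprintf("<synthetic_scene> %dx%d px, %.4g um/px, channels: %s (seed %d)\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", "), x$seed))
  invisible(x)
}

add_gaussian_noise <- function(px, sd) {
  if (sd <= 0) return(px)
  pmax(px + stats::rnorm(length(px), 0, sd), 0)
}

# distance of every pixel centre inside a bounding window to a polyline,
# returned together with the window indices
polyline_coverage <- function(verts, thickness_px, nr, nc, reach) {
  r0 <- max(1L, floor(min(verts[, 1]) - reach)); r1 <- min(nr, ceiling(max(verts[, 1]) + reach))
  c0 <- max(1L, floor(min(verts[, 2]) - reach)); c1 <- min(nc, ceiling(max(verts[, 2]) + reach))
  rows <- r0:r1; cols <- c0:c1
  pr <- matrix(rows, length(rows), length(cols))
  pc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  d <- matrix(Inf, length(rows), length(cols))
  for (k in seq_len(nrow(verts) - 1L)) {
    a <- verts[k, ]; b <- verts[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dk <- sqrt((pr - a[1])^2 + (pc - a[2])^2)
    } else {
      t <- ((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      dk <- sqrt((pr - (a[1] + t * ab[1]))^2 + (pc - (a[2] + t * ab[2]))^2)
    }
    d <- pmin(d, dk)
  }
  list(rows = rows, cols = cols, dist = d)
}

#' Simulate a hyaluronan fiber scene
#'
#' Draws `n_fibers` non-overlapping cable-like fibers (random polylines with
#' 0-3 bends, rasterized with anti-aliasing at the requested thickness) on a
#' dark background, emulating the dense interstitial matrix of ischemic
#' areas. The truth records each fiber's polyline and its exact arc length in
#' micrometres, computed on the polyline rather than the raster.
#'
#' @param n_fibers Number of fibers to place.
#' @param length_um Mean fiber arc length (um).
#' @param length_sd_um Standard deviation of fiber length (um); 0 gives
#'   fixed-length fibers.
#' @param thickness_px Fiber thickness in pixels.
#' @param image_size Image side in pixels (square field).
#' @param pixel_size_um Pixel size (um/px).
#' @param noise_sd Additive Gaussian noise s.d. (intensity units), clipped at 0.
#' @param amplitude Peak fiber intensity (a.u.).
#' @param n_bends Candidate bend counts, sampled per fiber (use `0` for
#'   straight fibers).
#' @param separation_px Minimum raster gap kept between fibers.
#' @param max_tries Placement attempts per fiber before failing.
#' @param seed Integer seed; same seed, same scene.
#' @return A `synthetic_scene` with an `HABP` channel and fiber truth.
#' @export
make_fiber_scene <- function(n_fibers, length_um = 9, length_sd_um = 0,
                             thickness_px = 3, image_size = 1024,
                             pixel_size_um = 0.09, noise_sd = 0,
                             amplitude = 200, n_bends = 0:2,
                             separation_px = 4, max_tries = 200L, seed = 1L) {
  stopifnot(n_fibers >= 1, length_um > 0, thickness_px >= 1)
  check_pixel_size(pixel_size_um)
  withr::with_seed(as.integer(seed), {
    nr <- nc <- as.integer(image_size)
    img <- matrix(0, nr, nc)
    blocked <- matrix(FALSE, nr, nc)
    half <- thickness_px / 2
    reach <- half + separation_px
    margin <- ceiling(reach) + 2L
    fibers <- vector("list", n_fibers)
    for (i in seq_len(n_fibers)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        L_um <- max(pixel_size_um, stats::rnorm(1, length_um, length_sd_um))
        if (length_sd_um == 0) L_um <- length_um
        L_px <- L_um / pixel_size_um
        k <- if (length(n_bends) == 1L) n_bends else sample(n_bends, 1L)
        fr <- stats::runif(k + 1L, 0.5, 1.5); fr <- fr / sum(fr)
        theta <- stats::runif(1, 0, 2 * pi)
        dth <- if (k > 0) stats::runif(k, -0.7, 0.7) else numeric(0)
        angs <- cumsum(c(theta, dth))
        start <- c(stats::runif(1, margin, nr - margin),
                   stats::runif(1, margin, nc - margin))
        steps <- cbind(fr * L_px * cos(angs), fr * L_px * sin(angs))
        cums <- matrix(c(cumsum(steps[, 1]), cumsum(steps[, 2])), ncol = 2)
        verts <- rbind(start, sweep(cums, 2, start, "+"))
        if (min(verts) < margin || max(verts[, 1]) > nr - margin ||
            max(verts[, 2]) > nc - margin) next
        cov <- polyline_coverage(verts, thickness_px, nr, nc, reach + 1)
        hit <- cov$dist <= reach
        if (any(blocked[cov$rows, cov$cols][hit])) next
        alpha <- pmin(pmax(half + 0.5 - cov$dist, 0), 1)
        img[cov$rows, cov$cols] <- pmax(img[cov$rows, cov$cols],
                                        amplitude * alpha)
        blocked[cov$rows, cov$cols] <- blocked[cov$rows, cov$cols] | hit
        fibers[[i]] <- list(fiber = i, length_um = L_um, vertices = verts)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place fiber ", i, " of ", n_fibers,
             " without overlap within the retry budget", call. = FALSE)
      }
    }
    img <- add_gaussian_noise(img, noise_sd)
    truth <- list(
      fibers = tibble::tibble(
        fiber = vapply(fibers, function(f) as.integer(f$fiber), integer(1)),
        length_um = vapply(fibers, `[[`, numeric(1), "length_um"),
        vertices = lapply(fibers, `[[`, "vertices")
      )
    )
    new_synthetic_scene(
      list(HABP = calibrated_image(img, pixel_size_um, "HABP")),
      truth, pixel_size_um, as.integer(seed)
    )
  })
}

#' Deterministic patterns of known box-counting dimension
#'
#' Analytic oracles for the fractal-dimension stage: a one-pixel-wide line
#' (dimension 1), a filled square (dimension 2) and the Sierpinski carpet
#' (dimension log 8 / log 3 = 1.8928). The carpet of `order` k on a
#' `3^k`-pixel grid contains exactly `8^k` foreground pixels.
#'
#' @param kind One of `"line"`, `"filled_square"`, `"sierpinski_carpet"`.
#' @param order Iteration count (carpet only).
#' @param size Image side in pixels; the carpet requires `size == 3^order`.
#' @param pixel_size_um Pixel size attached to the mask (default 1).
#' @return A [binary_mask()].
#' @export
make_fractal_pattern <- function(kind = c("line", "filled_square", "sierpinski_carpet"),
                                 order = NULL, size, pixel_size_um = 1) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  stopifnot(size >= 3L)
  px <- switch(kind,
    line = {
      m <- matrix(FALSE, size, size)
      m[ceiling(size / 2), ] <- TRUE
      m
    },
    filled_square = matrix(TRUE, size, size),
    sierpinski_carpet = {
      if (is.null(order) || order < 1L) {
        stop("sierpinski_carpet requires a positive order", call. = FALSE)
      }
      if (size != 3L^order) {
        stop("sierpinski_carpet requires size == 3^order (got size ", size,
             ", order ", order, ")", call. = FALSE)
      }
      base <- matrix(1, 3, 3); base[2, 2] <- 0
      m <- Reduce(kronecker, rep(list(base), order))
      m != 0
    }
  )
  binary_mask(px, pixel_size_um)
}

#' Simulate astrocytes with membrane-bound and punctate hyaluronan
#'
#' Places non-overlapping, fully interior cell disks (Thbs4 channel), an
#' optional one-pixel hyaluronan ring on each cell perimeter (membrane-bound
#' HA), circular HABP spots strictly inside cells (intracellular) and in the
#' background (extracellular), and CD44 puncta inside a stated fraction of
#' cells. Spot placement keeps an interior margin so that intracellular
#' spots fall inside the intracellular compartment for the default 1 um
#' band, and keeps spots mutually disjoint so recovered counts are exact.
#'
#' @param n_cells Number of cell disks.
#' @param radius_px Cell radius in pixels.
#' @param membrane_signal Draw the perimeter HA ring?
#' @param n_intra_spots Intracellular HABP spots per cell.
#' @param n_extra_spots Extracellular HABP spots in the background.
#' @param spot_radius_px Spot radius in pixels.
#' @param cd44_positive_fraction Fraction of cells given intracellular CD44
#'   puncta; `round(fraction * n_cells)` cells are flagged.
#' @param n_cd44_puncta CD44 puncta per positive cell.
#' @param image_size Image side in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param noise_sd Additive Gaussian noise s.d.
#' @param amplitude Foreground intensity (a.u.).
#' @param interior_margin_px Minimum distance of intracellular spot centres
#'   from the cell boundary (default keeps spots clear of an 11 px band).
#' @param seed Integer seed.
#' @return A `synthetic_scene` with `Thbs4`, `HABP` and (when any cell is
#'   CD44-positive) `CD44` channels plus cell/spot truth.
#' @export
make_cell_scene <- function(n_cells, radius_px = 55, membrane_signal = FALSE,
                            n_intra_spots = 0, n_extra_spots = 0,
                            spot_radius_px = 2, cd44_positive_fraction = 0,
                            n_cd44_puncta = 3, image_size = 1024,
                            pixel_size_um = 0.09, noise_sd = 0,
                            amplitude = 200, interior_margin_px = NULL,
                            seed = 1L) {
  stopifnot(n_cells >= 1, radius_px >= 3)
  check_pixel_size(pixel_size_um)
  withr::with_seed(as.integer(seed), {
    nr <- nc <- as.integer(image_size)
    band_px <- um_to_px(1.0, pixel_size_um)
    if (is.null(interior_margin_px)) {
      interior_margin_px <- band_px + spot_radius_px + 2L
    }
    if (radius_px <= interior_margin_px + spot_radius_px && n_intra_spots > 0) {
      stop("cells too small to hold intracellular spots clear of the membrane band",
           call. = FALSE)
    }
    border_margin <- radius_px + band_px + 4L
    min_center_gap <- 2 * radius_px + 2 * band_px + 6
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < n_cells) {
      tries <- tries + 1L
      if (tries > 500L * n_cells) {
        stop("could not place ", n_cells, " non-overlapping cells in a ",
             nr, "x", nc, " image", call. = FALSE)
      }
      cand <- c(stats::runif(1, border_margin, nr - border_margin),
                stats::runif(1, border_margin, nc - border_margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_center_gap)) {
        centers <- rbind(centers, cand)
      }
    }
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    thbs4 <- matrix(0, nr, nc)
    habp <- matrix(0, nr, nc)
    cd44 <- matrix(0, nr, nc)
    n_pos <- as.integer(round(cd44_positive_fraction * n_cells))
    pos_cells <- if (n_pos > 0) sort(sample.int(n_cells, n_pos)) else integer(0)

    spots <- list()
    occupied <- matrix(FALSE, nr, nc) # spot-disjointness bookkeeping
    place_spot <- function(center, compartment, cell, channel) {
      d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
      disk <- d <= spot_radius_px
      # keep a >1 px gap so spots stay 8-disconnected and counts are exact
      if (any(occupied & (d <= spot_radius_px + 2))) return(NULL)
      occupied <<- occupied | disk
      if (channel == "HABP") habp[disk] <<- amplitude else cd44[disk] <<- amplitude
      list(row = center[1], col = center[2], radius_px = spot_radius_px,
           compartment = compartment, cell = cell, channel = channel)
    }
    sample_inside <- function(center, max_r) {
      repeat {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- max_r * sqrt(stats::runif(1))
        return(center + rad * c(cos(ang), sin(ang)))
      }
    }

    for (i in seq_len(n_cells)) {
      ctr <- centers[i, ]
      d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
      thbs4[d <= radius_px] <- amplitude
      if (membrane_signal) {
        ring <- d <= radius_px & d > radius_px - 1
        habp[ring] <- amplitude
      }
      placed <- 0L
      guard <- 0L
      while (placed < n_intra_spots) {
        guard <- guard + 1L
        if (guard > 500L * max(1L, n_intra_spots)) {
          stop("could not seed intracellular spots in cell ", i, call. = FALSE)
        }
        p <- sample_inside(ctr, radius_px - interior_margin_px - spot_radius_px)
        s <- place_spot(p, "intracellular", i, "HABP")
        if (!is.null(s)) { spots[[length(spots) + 1L]] <- s; placed <- placed + 1L }
      }
      if (i %in% pos_cells) {
        placed <- 0L; guard <- 0L
        while (placed < n_cd44_puncta) {
          guard <- guard + 1L
          if (guard > 2000L) stop("could not seed CD44 puncta in cell ", i, call. = FALSE)
          p <- sample_inside(ctr, radius_px - interior_margin_px - spot_radius_px)
          s <- place_spot(p, "intracellular", i, "CD44")
          if (!is.null(s)) { spots[[length(spots) + 1L]] <- s; placed <- placed + 1L }
        }
      }
    }

    # extracellular spots: clear of every cell's band and of the border
    placed <- 0L; guard <- 0L
    clearance <- radius_px + band_px + spot_radius_px + 4
    while (placed < n_extra_spots) {
      guard <- guard + 1L
      if (guard > 500L * max(1L, n_extra_spots)) {
        stop("could not seed extracellular spots", call. = FALSE)
      }
      cand <- c(stats::runif(1, spot_radius_px + 2, nr - spot_radius_px - 2),
                stats::runif(1, spot_radius_px + 2, nc - spot_radius_px - 2))
      if (all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= clearance)) {
        s <- place_spot(cand, "extracellular", NA_integer_, "HABP")
        if (!is.null(s)) { spots[[length(spots) + 1L]] <- s; placed <- placed + 1L }
      }
    }

    thbs4 <- add_gaussian_noise(thbs4, noise_sd)
    habp <- add_gaussian_noise(habp, noise_sd)
    channels <- list(
      Thbs4 = calibrated_image(thbs4, pixel_size_um, "Thbs4"),
      HABP = calibrated_image(habp, pixel_size_um, "HABP")
    )
    if (n_pos > 0) {
      channels$CD44 <- calibrated_image(add_gaussian_noise(cd44, noise_sd),
                                        pixel_size_um, "CD44")
    }
    spot_tbl <- if (length(spots) == 0) {
      tibble::tibble(spot = integer(0), row = numeric(0), col = numeric(0),
                     radius_px = numeric(0), compartment = character(0),
                     cell = integer(0), channel = character(0))
    } else {
      tibble::tibble(
        spot = seq_along(spots),
        row = vapply(spots, `[[`, numeric(1), "row"),
        col = vapply(spots, `[[`, numeric(1), "col"),
        radius_px = vapply(spots, `[[`, numeric(1), "radius_px"),
        compartment = vapply(spots, `[[`, character(1), "compartment"),
        cell = vapply(spots, function(s) as.integer(s$cell), integer(1)),
        channel = vapply(spots, `[[`, character(1), "channel")
      )
    }
    truth <- list(
      cells = tibble::tibble(cell = seq_len(n_cells),
                             row = centers[, 1], col = centers[, 2],
                             radius_px = radius_px,
                             cd44_positive = seq_len(n_cells) %in% pos_cells),
      spots = spot_tbl,
      cd44_positive_fraction = if (n_cells > 0) n_pos / n_cells else 0
    )
    new_synthetic_scene(channels, truth, pixel_size_um, as.integer(seed))
  })
}

#' Simulate a ring-shaped ischemic lesion
#'
#' Builds a lesion geometry around the image centre: a core disk, a scar
#' annulus between `scar_inner_um` and `scar_outer_um`, and the tissue
#' beyond. Each requested channel receives intensity in its assigned
#' zone(s), emulating marker placement such as GFAP in core+scar and Thbs4
#' restricted to the scar annulus.
#'
#' @param core_radius_um Core radius (um).
#' @param scar_inner_um,scar_outer_um Scar annulus bounds (um); radii must be
#'   strictly increasing and fit within half the image extent.
#' @param channel_profiles Named list mapping channel label to a character
#'   vector of zones among `"core"`, `"scar"`, `"beyond"`.
#' @param image_size Image side in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param noise_sd Additive Gaussian noise s.d.
#' @param amplitude Foreground intensity (a.u.).
#' @param seed Integer seed.
#' @return A `synthetic_scene` with one channel per profile entry and the
#'   lesion radii in `truth$lesion`.
#' @export
make_lesion_scene <- function(core_radius_um, scar_inner_um, scar_outer_um,
                              channel_profiles = list(GFAP = c("core", "scar"),
                                                      Thbs4 = "scar"),
                              image_size = 512, pixel_size_um = 0.9,
                              noise_sd = 0, amplitude = 200, seed = 1L) {
  check_pixel_size(pixel_size_um)
  if (!(core_radius_um < scar_inner_um && scar_inner_um < scar_outer_um)) {
    stop("lesion radii must satisfy core < scar inner < scar outer",
         call. = FALSE)
  }
  nr <- nc <- as.integer(image_size)
  half_extent_um <- (min(nr, nc) / 2) * pixel_size_um
  if (scar_outer_um >= half_extent_um) {
    stop("scar outer radius (", scar_outer_um,
         " um) must be smaller than half the image extent (",
         half_extent_um, " um)", call. = FALSE)
  }
  stopifnot(length(channel_profiles) >= 1)
  withr::with_seed(as.integer(seed), {
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dist_um <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) * pixel_size_um
    zones <- list(
      core = dist_um <= core_radius_um,
      scar = dist_um >= scar_inner_um & dist_um <= scar_outer_um,
      beyond = dist_um > scar_outer_um
    )
    channels <- purrr::imap(channel_profiles, function(zz, ch) {
      bad <- setdiff(zz, names(zones))
      if (length(bad) > 0) stop("unknown lesion zone: ", bad[1], call. = FALSE)
      px <- matrix(0, nr, nc)
      for (z in zz) px[zones[[z]]] <- amplitude
      calibrated_image(add_gaussian_noise(px, noise_sd), pixel_size_um, ch)
    })
    truth <- list(lesion = list(
      center_row = ctr[1], center_col = ctr[2],
      core_radius_um = core_radius_um,
      scar_inner_um = scar_inner_um, scar_outer_um = scar_outer_um,
      scar_mid_um = (scar_inner_um + scar_outer_um) / 2
    ))
    new_synthetic_scene(channels, truth, pixel_size_um, as.integer(seed))
  })
}

#' Write a synthetic scene to disk
#'
#' Saves every channel as a calibrated TIFF (via [write_image()]) and the
#' ground truth as JSON, for use from the command line or for archiving
#' benchmark scenes.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(scene$channels)) {
    write_image(scene$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  }
  truth <- scene$truth
  if (!is.null(truth$fibers)) {
    truth$fibers <- dplyr::select(truth$fibers, -dplyr::any_of("vertices"))
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
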