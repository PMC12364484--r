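#' Calibrated fluorescence image
#'
#' A `calibrated_image` couples a 2D grid of non-negative intensities with the
#' physical pixel size (in micrometres) and a free-text marker label
#' ("HABP", "Thbs4", "GFAP", "Nestin", "CD44", ...). All pipeline stages
#' consume this container, so micrometre-valued outputs are always derived
#' from the calibration rather than raw pixel counts.
#'
#' Pixels are indexed `[row, col]` (1-based); the physical centre of pixel
#' `[i, j]` is at `((i - 0.5) * s, (j - 0.5) * s)` with `s = pixel_size_um`.
#' Pixels are assumed isotropic.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities with at
#'   least 2 rows and 2 columns.
#' @param pixel_size_um Physical edge length of one pixel, in micrometres
#'   (must be > 0). Confocal data in this domain is typically ~0.09 um/px.
#' @param channel Marker label carried along for bookkeeping.
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(matrix(runif(64), 8, 8), pixel_size_um = 0.09, "HABP")
#' img
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image grid must have at least 2 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("image intensities must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("image intensities must be non-negative", call. = FALSE)
  }
  check_pixel_size(pixel_size_um)
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         channel = as.character(channel)[1]),
    class = "calibrated_image"
  )
}

#' Binary segmentation mask
#'
#' Logical grid sharing the shape and calibration of the image it was derived
#' from. Its physical area is `sum(pixels) * pixel_size_um^2`.
#'
#' @param pixels Logical (or 0/1 numeric) matrix.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  if (is.numeric(pixels)) pixels <- pixels != 0
  if (!is.logical(pixels)) stop("mask pixels must be logical or 0/1", call. = FALSE)
  if (anyNA(pixels)) stop("mask pixels must not contain NA", call. = FALSE)
  check_pixel_size(pixel_size_um)
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
    class = "binary_mask"
  )
}

#' Mask area in square micrometres
#'
#' @param mask A [binary_mask()].
#' @return Area of the foreground in um^2.
#' @export
mask_area_um2 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$pixels) * mask$pixel_size_um^2
}

#' Labelled cell map
#'
#' Integer grid with 0 = background and labels `1..K` identifying connected
#' cell regions (8-connectivity). Labels are always relabelled to a contiguous
#' set on construction.
#'
#' @param pixels Integer matrix of non-negative labels.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class `label_map`.
#' @export
label_map <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels != round(pixels))) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  check_pixel_size(pixel_size_um)
  pixels <- relabel_contiguous(pixels)
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
    class = "label_map"
  )
}

#' Number of labelled cells in a label map
#' @param cells A [label_map()].
#' @return Integer count of distinct positive labels.
#' @export
n_cells <- function(cells) {
  stopifnot(inherits(cells, "label_map"))
  max(cells$pixels)
}

relabel_contiguous <- function(px) {
  labs <- sort(unique(px[px > 0]))
  if (length(labs) == 0L) {
    storage.mode(px) <- "integer"
    return(px)
  }
  out <- match(px, labs, nomatch = 0L)
  dim(out) <- dim(px)
  storage.mode(out) <- "integer"
  out
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number", call. = FALSE)
  }
  invisible(pixel_size_um)
}

#' Convert a physical length to a pixel count
#'
#' Rounds half-up and never returns less than one pixel, so that the 1 um
#' membrane band at 0.09 um pixels maps to 11 px.
#'
#' @param length_um Length in micrometres (> 0).
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @return Integer number of pixels (>= 1).
#' @examples
#' um_to_px(1.0, 0.09) # 11
#' @export
um_to_px <- function(length_um, pixel_size_um) {
  if (!is.numeric(length_um) || any(length_um <= 0)) {
    stop("length_um must be positive", call. = FALSE)
  }
  check_pixel_size(pixel_size_um)
  max(1L, as.integer(floor(length_um / pixel_size_um + 0.5)))
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %dx%d px, %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d px, %.4g um/px, %d foreground px (%.4g um^2)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$pixels), mask_area_um2(x)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %dx%d px, %.4g um/px, %d cells\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, n_cells(x)))
  invisible(x)
}

# shared shape check used by stages combining several grids
check_same_shape <- function(a, b) {
  da <- dim(if (is.list(a)) a$pixels else a)
  db <- dim(if (is.list(b)) b$pixels else b)
  if (!identical(da, db)) {
    stop("grids have mismatching shapes (", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}
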