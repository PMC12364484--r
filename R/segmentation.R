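#' Automatic threshold for a calibrated image
#'
#' Computes the segmentation threshold for the hyaluronan (HABP) or cell
#' channel. `"otsu"` (the default, and the FIJI default) maximizes
#' between-class variance on a 256-bin histogram spanning the image's own
#' intensity range, which makes the resulting mask invariant under positive
#' rescaling of intensities. `"percentile"` thresholds at the `p`-th
#' intensity percentile; `"fixed"` uses the supplied value `t`. Both
#' alternatives exist for sensitivity analysis.
#'
#' @param image A [calibrated_image()].
#' @param method `"otsu"`, `"percentile"` or `"fixed"`.
#' @param p Percentile in (0, 100) for `method = "percentile"`.
#' @param t Threshold intensity for `method = "fixed"`.
#' @return A single threshold; pixels strictly above it are foreground.
#' @export
threshold_value <- function(image, method = c("otsu", "percentile", "fixed"),
                            p = 99, t = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method)
  px <- image$pixels
  switch(method,
    otsu = {
      rng <- range(px)
      if (rng[1] == rng[2]) {
        stop("otsu threshold undefined for a constant image", call. = FALSE)
      }
      EBImage::otsu(EBImage::Image(px), range = rng, levels = 256L)
    },
    percentile = {
      if (!is.numeric(p) || p <= 0 || p >= 100) {
        stop("percentile must lie strictly between 0 and 100", call. = FALSE)
      }
      as.numeric(stats::quantile(px, p / 100, names = FALSE))
    },
    fixed = {
      if (is.null(t) || !is.finite(t)) {
        stop("method 'fixed' requires a finite threshold t", call. = FALSE)
      }
      as.numeric(t)
    }
  )
}

#' Segment the hyaluronan matrix signal
#'
#' Thresholds the HABP channel (automatic threshold by default) and removes
#' connected components smaller than `min_object_px` pixels
#' (8-connectivity), yielding the binary matrix mask that the skeleton,
#' fractal and compartment stages consume.
#'
#' @inheritParams threshold_value
#' @param min_object_px Minimum component size kept, in pixels.
#' @return A list with `mask` (a [binary_mask()]) and `report`, a one-row
#'   tibble recording the method, the threshold and the surviving
#'   foreground fraction.
#' @examples
#' sc <- make_fiber_scene(5, length_um = 6, image_size = 256, seed = 1)
#' seg <- segment_matrix(sc$channels$HABP)
#' seg$report
#' @export
segment_matrix <- function(image, method = c("otsu", "percentile", "fixed"),
                           p = 99, t = NULL, min_object_px = 4L) {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method)
  thr <- threshold_value(image, method, p = p, t = t)
  fg <- image$pixels > thr
  fg <- remove_small_components(fg, as.integer(min_object_px))
  report <- tibble::tibble(
    method = method,
    threshold = as.numeric(thr),
    foreground_fraction = mean(fg)
  )
  list(mask = binary_mask(fg, image$pixel_size_um), report = report)
}

#' Segment cell bodies into a label map
#'
#' Thresholds the cell channel (Thbs4 in the scar analysis), optionally
#' fills holes (so membrane-dominant staining still yields solid cell
#' bodies), labels 8-connected components, removes regions smaller than
#' `min_area_um2`, and optionally removes cells touching the image border
#' (partial membranes bias per-cell compartment areas).
#'
#' @inheritParams threshold_value
#' @param min_area_um2 Minimum cell area kept, in um^2.
#' @param fill_holes Fill enclosed holes before labelling?
#' @param exclude_border Drop regions touching the image border?
#' @return A [label_map()] with labels `1..K`.
#' @export
segment_cells <- function(image, method = c("otsu", "percentile", "fixed"),
                          p = 99, t = NULL, min_area_um2 = 20,
                          fill_holes = TRUE, exclude_border = TRUE) {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method)
  thr <- threshold_value(image, method, p = p, t = t)
  fg <- image$pixels > thr
  if (fill_holes) fg <- fill_mask_holes(fg)
  lab <- label_components_8(fg)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    min_px <- min_area_um2 / image$pixel_size_um^2
    drop <- sizes < min_px
    if (exclude_border) {
      border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                                lab[, 1], lab[, ncol(lab)]))
      drop[border_labels[border_labels > 0L]] <- TRUE
    }
    lab[lab > 0L & drop[pmax(lab, 1L)]] <- 0L
  }
  label_map(lab, image$pixel_size_um)
}
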