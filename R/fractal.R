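#' Box counts of a binary mask
#'
#' For each box size `eps` the grid is tiled from the origin into
#' `eps x eps` boxes (partial boxes at the far edges count) and the number
#' of boxes containing at least one foreground pixel is returned. A single
#' fixed tiling origin is used, matching the simple tiling of the FIJI
#' fractal-count plugin and keeping counts exactly reproducible.
#'
#' @param mask A non-empty [binary_mask()].
#' @param sizes Integer vector of box sizes, each between 1 and
#'   `min(nrow, ncol)`.
#' @return Integer vector of occupied-box counts, one per size.
#' @export
box_count <- function(mask, sizes) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  if (!any(px)) stop("cannot box-count an empty mask", call. = FALSE)
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(sizes < 1L) || any(sizes > min(dim(px)))) {
    stop("box sizes must lie between 1 and min(height, width)", call. = FALSE)
  }
  vapply(sizes, function(eps) {
    rg <- (seq_len(nrow(px)) - 1L) %/% eps
    cg <- (seq_len(ncol(px)) - 1L) %/% eps
    occ_rows <- rowsum(px * 1, rg)           # rows collapsed into bands
    occ <- t(rowsum(t(occ_rows), cg))        # columns collapsed into boxes
    sum(occ > 0)
  }, integer(1))
}

#' Box-counting fractal dimension
#'
#' Fits the slope of `log(count)` against `log(1/size)` by ordinary least
#' squares -- the matrix-interconnectivity index applied to the
#' skeletonized/segmented hyaluronan signal. Unless `sizes` is given, box
#' sizes are powers of 2 from 2 px up to `min(H, W) / 4`; when the mask
#' side is itself a power of 3 (the analytic carpet patterns), powers of 3
#' from 3 px to `min(H, W) / 3` are used so that the theoretical counts are
#' hit exactly. The raw slope is clipped to the planar range `[0, 2]` and
#' flagged when clipping occurred.
#'
#' @param mask A non-empty [binary_mask()].
#' @param sizes Optional explicit box-size schedule (at least 3 sizes).
#' @return A `fractal_fit` object; see [tidy.fractal_fit()] and
#'   [glance.fractal_fit()].
#' @examples
#' fit <- fractal_dim(make_fractal_pattern("sierpinski_carpet", 4, 81))
#' glance(fit)
#' @export
fractal_dim <- function(mask, sizes = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(sizes)) {
    m <- min(dim(mask$pixels))
    if (is_power_of(m, 3L)) {
      kmax <- floor(log(m / 3) / log(3))
      sizes <- 3L^seq(1L, max(1L, kmax))
    } else {
      kmax <- floor(log2(m / 4))
      sizes <- 2L^seq(1L, max(1L, kmax))
    }
  }
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  if (length(sizes) < 3L) {
    stop("fractal fit needs at least 3 box sizes", call. = FALSE)
  }
  counts <- box_count(mask, sizes)
  fit <- stats::lm(log(counts) ~ I(log(1 / sizes)))
  slope <- unname(stats::coef(fit)[2])
  # analytic patterns fit exactly; the perfect-fit warning is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  clipped <- slope < 0 || slope > 2
  structure(
    list(box_sizes_px = sizes, box_counts = counts,
         dimension = min(max(slope, 0), 2), raw_slope = slope,
         clipped = clipped, r_squared = r2),
    class = "fractal_fit"
  )
}

is_power_of <- function(n, b) {
  k <- round(log(n) / log(b))
  b^k == n
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> dimension %.4f (R^2 %.4f, %d box sizes%s)\n",
              x$dimension, x$r_squared, length(x$box_sizes_px),
              if (x$clipped) ", slope clipped" else ""))
  invisible(x)
}

#' Tidy a fractal fit into its size/count table
#'
#' @param x A `fractal_fit`.
#' @param ... Unused.
#' @return A tibble with one row per box size: `box_size_px`, `box_count`,
#'   `log_inv_size`, `log_count`.
#' @method tidy fractal_fit
#' @export
tidy.fractal_fit <- function(x, ...) {
  tibble::tibble(box_size_px = x$box_sizes_px, box_count = x$box_counts,
                 log_inv_size = log(1 / x$box_sizes_px),
                 log_count = log(x$box_counts))
}

#' One-row summary of a fractal fit
#'
#' @param x A `fractal_fit`.
#' @param ... Unused.
#' @return A tibble with `dimension`, `r_squared`, `n_sizes`, `clipped`.
#' @method glance fractal_fit
#' @export
glance.fractal_fit <- function(x, ...) {
  tibble::tibble(dimension = x$dimension, r_squared = x$r_squared,
                 n_sizes = length(x$box_sizes_px), clipped = x$clipped)
}

#' Log-log plot of a box-counting fit
#'
#' @param object A `fractal_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fractal_fit
#' @export
autoplot.fractal_fit <- function(object, ...) {
  df <- tidy.fractal_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_inv_size, y = .data$log_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = "log(1 / box size)", y = "log(occupied boxes)",
      title = sprintf("Box-counting dimension %.3f (R² = %.3f)",
                      object$dimension, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
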