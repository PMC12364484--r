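#' Read a calibrated TIFF image
#'
#' Reads one plane of a (possibly multi-plane) TIFF and attaches the physical
#' pixel size. Calibration is resolved in priority order: TIFF resolution
#' tags (XResolution with a cm or inch unit, as written by microscope
#' software), a JSON calibration sidecar written by [write_image()], and
#' finally the `pixel_size_um` override. With none of the three the read
#' fails, because downstream micrometre measures would be meaningless.
#'
#' @param path Path to a TIFF file.
#' @param channel Marker label to attach ("HABP", "Thbs4", ...). Defaults to
#'   the sidecar's stored channel, when present.
#' @param pixel_size_um Optional calibration override in um/px.
#' @param plane Plane index for multi-plane files (default 1).
#' @return A [calibrated_image()].
#' @seealso [write_image()]
#' @export
read_image <- function(path, channel = NULL, pixel_size_um = NULL, plane = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (plane < 1L || plane > length(planes)) {
    stop("plane ", plane, " out of range; file has ", length(planes),
         " plane(s)", call. = FALSE)
  }
  img <- planes[[plane]]
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L] else
      stop("multi-sample plane is not a single grayscale channel; ",
           "split channels into separate planes or files", call. = FALSE)
  }
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  pixels <- matrix(round(as.numeric(img) * (2^bits - 1)),
                   nrow(img), ncol(img))

  meta_px <- tiff_pixel_size_um(img)
  sidecar <- read_calibration_sidecar(path)
  if (!is.null(pixel_size_um)) {
    px_um <- pixel_size_um
  } else if (!is.null(meta_px)) {
    px_um <- meta_px
  } else if (!is.null(sidecar$pixel_size_um)) {
    px_um <- sidecar$pixel_size_um
  } else {
    stop("pixel size unknown: no resolution metadata, no calibration ",
         "sidecar and no override supplied for ", path, call. = FALSE)
  }
  if (is.null(channel)) {
    channel <- if (!is.null(sidecar$channel)) sidecar$channel else ""
  }
  calibrated_image(pixels, pixel_size_um = px_um, channel = channel)
}

# XResolution/ResolutionUnit -> um per pixel; anisotropic calibration is an
# error rather than being silently averaged.
tiff_pixel_size_um <- function(img) {
  xres <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (is.null(xres) || is.null(unit) || !is.finite(xres) || xres <= 0) {
    return(NULL)
  }
  yres <- attr(img, "y.resolution")
  if (!is.null(yres) && is.finite(yres) && yres > 0 &&
      abs(yres - xres) > 1e-6 * xres) {
    stop("anisotropic pixel calibration in TIFF metadata is not supported",
         call. = FALSE)
  }
  um_per_unit <- switch(as.character(unit), cm = 1e4, inch = 25400, NULL)
  if (is.null(um_per_unit)) return(NULL)
  um_per_unit / xres
}

sidecar_path <- function(path) paste0(path, ".calib.json")

read_calibration_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a calibrated image as 16-bit TIFF
#'
#' Intensities must lie in `[0, 65535]`; integer intensities round-trip
#' losslessly through [read_image()]. Because baseline TIFF writers in R do
#' not expose resolution tags, the calibration (pixel size and channel label)
#' is stored in a small JSON sidecar next to the image, which [read_image()]
#' picks up automatically; TIFF resolution tags present in files from other
#' sources still take precedence.
#'
#' @param image A [calibrated_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  if (max(image$pixels) > 65535) {
    stop("intensities exceed the 16-bit range [0, 65535]", call. = FALSE)
  }
  ok <- try(tiff::writeTIFF(image$pixels / 65535, path,
                            bits.per.sample = 16L, compression = "none",
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write TIFF to ", path, call. = FALSE)
  }
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um, channel = image$channel),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write per-field results as a deterministic CSV
#'
#' Rows carry `field`, `condition`, `region`, `metric`, `value` and `units`
#' columns (the tabular backbone of every figure-level summary). Rows are
#' sorted by field then metric so the output bytes do not depend on the
#' order in which stages appended rows.
#'
#' @param rows Data frame of field results.
#' @param path Output CSV path.
#' @return The sorted tibble, invisibly.
#' @export
write_results <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0L) stop("no results to write", call. = FALSE)
  needed <- c("field", "condition", "region", "metric", "value", "units")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0L) {
    stop("results are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(rows$value))) stop("result values must be finite", call. = FALSE)
  rows <- dplyr::arrange(rows[, needed], .data$field, .data$metric)
  readr::write_csv(rows, path, progress = FALSE)
  invisible(rows)
}

#' Assemble one field-result row
#'
#' @param field,condition,region Identifying labels.
#' @param metric Metric name.
#' @param value Finite numeric value.
#' @param units Unit string ("" for dimensionless).
#' @return A one-row tibble.
#' @export
field_result <- function(field, condition, region, metric, value, units = "") {
  tibble::tibble(field = as.character(field), condition = as.character(condition),
                 region = as.character(region), metric = as.character(metric),
                 value = as.numeric(value), units = as.character(units))
}
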