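#' Run the full matrix-quantification pipeline
#'
#' Drives the whole analysis over a set of fields (images tagged with
#' condition and region labels): segment the hyaluronan matrix and,
#' when a cell channel is present, the astrocytes; skeletonize and
#' summarize cable lengths; fit the box-counting fractal dimension on the
#' skeletonized matrix; partition each field into intracellular / membrane
#' / extracellular compartments and quantify per-cell hyaluronan and CD44
#' internalization; optionally compute radial profiles; pool cable lengths
#' per condition into ECDFs and compare conditions by Kruskal-Wallis.
#' A field that fails at any stage is reported with its stage name while
#' the remaining fields are still processed. All CSV outputs are
#' deterministic for a given configuration and seed.
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#'   Recognized top-level keys: `pixel_size_um` (override), `band_width_um`
#'   (default 1), `threshold_method` (default `"otsu"`), `min_object_px`
#'   (4), `min_area_um2` (20), `min_spot_px` (3), `min_cd44_px` (5),
#'   `bin_um` (10), `seed` (1), `output_dir`, and `fields`: a list of
#'   entries with `id`, `condition`, `region`, `channels` (named
#'   channel-to-TIFF map with at least `HABP`) and optional `profile`
#'   (`center` = pixel coordinates, optional `channels`, `bin_um`,
#'   `max_radius_um`).
#' @param output_dir Overrides the configured output directory.
#' @return (Invisibly) a list with tibbles `results`, `skeletons`, `cells`,
#'   `ecdf`, `kw`, `profiles`, `errors` and the written file paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- load_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) stop("config must name an output_dir", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(cfg$seed)

  log_path <- file.path(cfg$output_dir, "run_log.txt")
  log_lines <- c(
    paste0("run started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("parameters: ",
           jsonlite::toJSON(cfg[setdiff(names(cfg), "fields")],
                            auto_unbox = TRUE, digits = NA)),
    paste0("fields: ", length(cfg$fields))
  )

  results <- list(); skeletons <- list(); cells_tbl <- list()
  profiles <- list(); errors <- list()

  for (fld in cfg$fields) {
    stage <- "config"
    res <- tryCatch({
      stopifnot(!is.null(fld$id), !is.null(fld$channels))
      cond <- fld$condition %||% "unknown"
      regn <- fld$region %||% "unknown"
      stage <- "read"
      chans <- purrr::imap(fld$channels, function(path, ch) {
        read_image(path, channel = ch,
                   pixel_size_um = fld$pixel_size_um %||% cfg$pixel_size_um)
      })
      if (is.null(chans$HABP)) stop("field has no HABP channel")
      rows <- list()
      stage <- "segment_matrix"
      seg <- segment_matrix(chans$HABP, method = cfg$threshold_method,
                            min_object_px = cfg$min_object_px)
      rows[[length(rows) + 1L]] <- field_result(
        fld$id, cond, regn, "ha_area_um2", mask_area_um2(seg$mask), "um2")

      stage <- "skeleton"
      sk <- summarize_skeletons(seg$mask)
      sk_tagged <- dplyr::mutate(sk, field = fld$id, condition = cond,
                                 region = regn, .before = 1)
      rows[[length(rows) + 1L]] <- field_result(
        fld$id, cond, regn, "mean_lsp_um", mean(sk$lsp_um), "um")
      rows[[length(rows) + 1L]] <- field_result(
        fld$id, cond, regn, "n_components", nrow(sk), "")

      stage <- "fractal"
      fr <- fractal_dim(skeletonize(seg$mask))
      rows[[length(rows) + 1L]] <- field_result(
        fld$id, cond, regn, "fractal_dimension", fr$dimension, "")

      cell_rec <- NULL
      if (!is.null(chans$Thbs4)) {
        stage <- "segment_cells"
        cmap <- segment_cells(chans$Thbs4, method = cfg$threshold_method,
                              min_area_um2 = cfg$min_area_um2)
        if (n_cells(cmap) > 0) {
          stage <- "compartments"
          comp <- compartmentalize(cmap, band_width_um = cfg$band_width_um)
          cd44_mask <- NULL
          if (!is.null(chans$CD44)) {
            cd44_mask <- segment_matrix(chans$CD44,
                                        method = cfg$threshold_method,
                                        min_object_px = cfg$min_object_px)$mask
          }
          cell_rec <- quantify_cells(cmap, comp, seg$mask, cd44_mask,
                                     min_spot_px = cfg$min_spot_px,
                                     min_cd44_px = cfg$min_cd44_px)
          cell_rec <- dplyr::mutate(cell_rec, field = fld$id,
                                    condition = cond, region = regn,
                                    .before = 1)
          rows[[length(rows) + 1L]] <- field_result(
            fld$id, cond, regn, "n_cells", n_cells(cmap), "")
          rows[[length(rows) + 1L]] <- field_result(
            fld$id, cond, regn, "membrane_ha_area_um2",
            sum(cell_rec$ha_membrane_um2), "um2")
          rows[[length(rows) + 1L]] <- field_result(
            fld$id, cond, regn, "intracellular_ha_area_um2",
            sum(cell_rec$ha_intracellular_um2), "um2")
          rows[[length(rows) + 1L]] <- field_result(
            fld$id, cond, regn, "intracellular_spots",
            sum(cell_rec$intracellular_spots), "")
          rows[[length(rows) + 1L]] <- field_result(
            fld$id, cond, regn, "extracellular_ha_um2",
            field_extracellular_ha(comp, seg$mask), "um2")
          if (!is.null(cd44_mask)) {
            rows[[length(rows) + 1L]] <- field_result(
              fld$id, cond, regn, "internalization_fraction",
              internalization_fraction(cell_rec), "")
          }
        }
      }

      prof_tbl <- NULL
      if (!is.null(fld$profile)) {
        stage <- "profile"
        pchans <- fld$profile$channels %||% names(chans)
        prof_tbl <- purrr::map_dfr(pchans, function(ch) {
          pr <- radial_profile(chans[[ch]],
                               center = unlist(fld$profile$center),
                               bin_um = fld$profile$bin_um %||% cfg$bin_um,
                               max_radius_um = fld$profile$max_radius_um)
          dplyr::mutate(tibble::as_tibble(pr), field = fld$id,
                        condition = cond, region = regn, .before = 1)
        })
        for (ch in pchans) {
          pk <- scar_peak(radial_profile(chans[[ch]],
                                         center = unlist(fld$profile$center),
                                         bin_um = fld$profile$bin_um %||% cfg$bin_um,
                                         max_radius_um = fld$profile$max_radius_um))
          rows[[length(rows) + 1L]] <- field_result(
            fld$id, cond, regn, paste0("peak_radius_", ch, "_um"), pk, "um")
        }
      }
      list(rows = dplyr::bind_rows(rows), skeletons = sk_tagged,
           cells = cell_rec, profiles = prof_tbl)
    }, error = function(e) {
      structure(list(field = fld$id %||% "?", stage = stage,
                     message = conditionMessage(e)), class = "field_error")
    })
    if (inherits(res, "field_error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        field = res$field, stage = res$stage, message = res$message)
      log_lines <- c(log_lines, sprintf("ERROR field %s at stage %s: %s",
                                        res$field, res$stage, res$message))
    } else {
      results[[length(results) + 1L]] <- res$rows
      skeletons[[length(skeletons) + 1L]] <- res$skeletons
      if (!is.null(res$cells)) cells_tbl[[length(cells_tbl) + 1L]] <- res$cells
      if (!is.null(res$profiles)) profiles[[length(profiles) + 1L]] <- res$profiles
    }
  }

  results <- dplyr::bind_rows(results)
  skeletons <- dplyr::bind_rows(skeletons)
  cells_tbl <- dplyr::bind_rows(cells_tbl)
  profiles <- dplyr::bind_rows(profiles)
  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(field = character(0), stage = character(0),
                   message = character(0))

  # condition-pooled ECDFs and the cross-condition Kruskal-Wallis test
  ecdf_tbl <- tibble::tibble(condition = character(0), value = numeric(0),
                             fraction = numeric(0))
  kw_tbl <- NULL
  if (nrow(skeletons) > 0) {
    ecdf_tbl <- skeletons |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(~ ecdf_table(.x$lsp_um)) |>
      dplyr::ungroup()
    if (dplyr::n_distinct(skeletons$condition) >= 2L &&
        nrow(skeletons) >= 3L) {
      kw <- kruskal_wallis(skeletons, lsp_um, condition)
      kw_tbl <- glance.group_comparison(kw)
    }
  }

  paths <- list(results = file.path(cfg$output_dir, "results.csv"),
                skeletons = file.path(cfg$output_dir, "skeletons.csv"),
                cells = file.path(cfg$output_dir, "cells.csv"),
                ecdf = file.path(cfg$output_dir, "ecdf.csv"),
                kw = file.path(cfg$output_dir, "kw.csv"),
                errors = file.path(cfg$output_dir, "errors.csv"),
                log = log_path)
  if (nrow(results) > 0) write_results(results, paths$results)
  readr::write_csv(skeletons, paths$skeletons, progress = FALSE)
  readr::write_csv(cells_tbl, paths$cells, progress = FALSE)
  readr::write_csv(ecdf_tbl, paths$ecdf, progress = FALSE)
  if (!is.null(kw_tbl)) readr::write_csv(kw_tbl, paths$kw, progress = FALSE)
  readr::write_csv(errors, paths$errors, progress = FALSE)
  log_lines <- c(log_lines,
                 sprintf("fields completed: %d, failed: %d",
                         dplyr::n_distinct(results$field), nrow(errors)))
  writeLines(log_lines, log_path)

  invisible(list(results = results, skeletons = skeletons, cells = cells_tbl,
                 ecdf = ecdf_tbl, kw = kw_tbl, profiles = profiles,
                 errors = errors, paths = paths))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  defaults <- list(band_width_um = 1.0, threshold_method = "otsu",
                   min_object_px = 4L, min_area_um2 = 20, min_spot_px = 3L,
                   min_cd44_px = 5L, bin_um = 10, seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  config$seed <- as.integer(config$seed)
  if (is.null(config$fields) || length(config$fields) == 0L) {
    stop("config lists no fields", call. = FALSE)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
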