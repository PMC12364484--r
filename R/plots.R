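#' Cumulative cable-length curves by condition
#'
#' Step-plot of the ECDF of skeleton longest-shortest-path lengths pooled
#' within each condition -- the visual comparison that the Kruskal-Wallis
#' test quantifies.
#'
#' @param skeletons Tibble of skeleton summaries carrying `lsp_um` and a
#'   `condition` column (e.g. the `skeletons` output of [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_length_ecdf <- function(skeletons) {
  skeletons <- tibble::as_tibble(skeletons)
  stopifnot(all(c("lsp_um", "condition") %in% names(skeletons)))
  df <- skeletons |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ ecdf_table(.x$lsp_um)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$fraction,
                                   colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cable length, longest shortest path (µm)",
                  y = "cumulative fraction", colour = "condition") +
    ggplot2::theme_minimal()
}

#' Display a compartment map
#'
#' @param object A `compartment_map`.
#' @param ... Unused.
#' @return A ggplot raster of the three compartments.
#' @method autoplot compartment_map
#' @export
autoplot.compartment_map <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$code)), times = ncol(object$code)),
    col = rep(seq_len(ncol(object$code)), each = nrow(object$code)),
    compartment = factor(c("intracellular", "membrane", "extracellular")[object$code],
                         levels = c("intracellular", "membrane", "extracellular"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$compartment)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
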