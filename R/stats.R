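#' Kruskal-Wallis comparison of cable-length distributions
#'
#' Nonparametric rank test used to compare cumulative distributions of
#' skeleton cable lengths (or any grouped values) across two or more
#' conditions: pooled mid-ranks, the tie-corrected H statistic, and a
#' p-value from the chi-squared upper tail with `k - 1` degrees of freedom.
#' All-identical values are legal and give `H = 0`, `p = 1`.
#'
#' @param data A data frame with a value column and a group column, or a
#'   (optionally named) list of at least two numeric vectors.
#' @param value,group Column names (tidy-eval) when `data` is a data frame.
#' @return A one-row `group_comparison` tibble: `n_groups`, `n_total`,
#'   `statistic` (H), `df`, `p_value`, plus a `groups` list-column with
#'   per-group sample sizes.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_wallis <- function(data, value = NULL, group = NULL) {
  if (is.data.frame(data)) {
    values <- dplyr::pull(data, {{ value }})
    groups <- as.factor(dplyr::pull(data, {{ group }}))
  } else if (is.list(data)) {
    if (is.null(names(data))) names(data) <- paste0("g", seq_along(data))
    values <- unlist(data, use.names = FALSE)
    groups <- factor(rep(names(data), lengths(data)), levels = names(data))
  } else {
    stop("data must be a data frame or a list of numeric vectors", call. = FALSE)
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(values) < 3L) stop("need at least 3 values in total", call. = FALSE)
  k <- nlevels(groups)
  if (length(unique(values)) == 1L) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  sizes <- tibble::tibble(group = levels(groups),
                          n = as.integer(table(groups)))
  out <- tibble::tibble(n_groups = k, n_total = length(values),
                        statistic = h, df = k - 1L, p_value = p,
                        groups = list(sizes))
  class(out) <- c("group_comparison", class(out))
  out
}

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::as_tibble(x[, c("n_groups", "n_total", "statistic", "df", "p_value")])
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Semi-quantification of target-gene expression normalized to a reference
#' (housekeeping) gene and a control condition:
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#'        (Ct_target,control - Ct_ref,control)` and fold change
#' `2^(-ddCt)`. All arguments vectorize, so a whole Ct table can be
#' processed at once.
#'
#' @param ct_target_treated,ct_ref_treated Ct of target and reference gene
#'   in the treated condition.
#' @param ct_target_control,ct_ref_control Ct of target and reference gene
#'   in the control condition.
#' @param sample Optional sample labels.
#' @return Tibble with `sample`, `dct_treated`, `dct_control`, `ddct`,
#'   `fold_change`.
#' @examples
#' ddct(22, 20, 24, 20) # fold change 4
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control, sample = NULL) {
  cts <- list(ct_target_treated, ct_ref_treated,
              ct_target_control, ct_ref_control)
  if (any(!vapply(cts, is.numeric, logical(1))) ||
      any(!is.finite(unlist(cts))) || any(unlist(cts) <= 0)) {
    stop("all Ct values must be finite and positive", call. = FALSE)
  }
  n <- max(lengths(cts))
  if (is.null(sample)) sample <- paste0("s", seq_len(n))
  dct_t <- ct_target_treated - ct_ref_treated
  dct_c <- ct_target_control - ct_ref_control
  dd <- dct_t - dct_c
  tibble::tibble(sample = as.character(sample),
                 dct_treated = dct_t, dct_control = dct_c,
                 ddct = dd, fold_change = 2^(-dd))
}

#' ddCt semi-quantification of a Ct table
#'
#' Data-frame front end to [ddct()]: expects columns
#' `ct_target_treated`, `ct_ref_treated`, `ct_target_control`,
#' `ct_ref_control` and optionally `sample`.
#'
#' @param data A data frame of Ct values.
#' @return Tibble as in [ddct()].
#' @export
ddct_table <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("ct_target_treated", "ct_ref_treated",
            "ct_target_control", "ct_ref_control")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ddct(data$ct_target_treated, data$ct_ref_treated,
       data$ct_target_control, data$ct_ref_control,
       sample = if ("sample" %in% names(data)) data$sample else NULL)
}
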