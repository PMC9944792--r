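#' Tidy and glance methods for analysis results
#'
#' `tidy()` returns the underlying per-test tibble; `glance()` a one-row
#' overview (tests run, significant or retained counts, family structure).
#'
#' @param x A `meth_comparisons` or `meth_correlations` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.meth_comparisons <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.meth_comparisons <- function(x, ...) {
  tbl <- as_tibble(x)
  tibble(
    n_tests = nrow(tbl),
    n_significant = sum(tbl$significant, na.rm = TRUE),
    n_families = dplyr::n_distinct(tbl$family),
    n_comparisons = dplyr::n_distinct(tbl$comparison),
    min_p = suppressWarnings(min(tbl$p_value, na.rm = TRUE))
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.meth_correlations <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.meth_correlations <- function(x, ...) {
  tbl <- as_tibble(x)
  tibble(
    n_screened = nrow(tbl),
    n_retained = sum(tbl$retained, na.rm = TRUE),
    n_groups = dplyr::n_distinct(tbl$group),
    n_covariates = dplyr::n_distinct(tbl$covariate),
    max_abs_rho = suppressWarnings(max(abs(tbl$rho), na.rm = TRUE))
  )
}

#' Box summary of per-site methylation by group
#'
#' @param matrix Methylation matrix with a `group` column.
#' @param panel Site panel.
#' @param sites Character vector of `site_id`s to show (default: up to 12
#'   panel sites present in the matrix).
#' @return A ggplot object.
#' @export
plot_site_methylation <- function(matrix, panel, sites = NULL) {
  present <- intersect(panel$site_id, names(matrix))
  sites <- sites %||% utils::head(present, 12)
  long <- matrix |>
    select("sample_id", "group", dplyr::all_of(sites)) |>
    tidyr::pivot_longer(dplyr::all_of(sites), names_to = "site_id",
                        values_to = "methylation") |>
    mutate(site_id = factor(.data$site_id, levels = sites))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site_id,
                                     y = .data$methylation,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::labs(x = NULL, y = "methylation (%)", fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.meth_comparisons <- function(object, ...) {
  tbl <- as_tibble(object)
  thresholds <- distinct(tbl, .data$family, .data$alpha_adjusted)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$label,
                                    y = -log10(.data$p_value),
                                    colour = .data$comparison,
                                    shape = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = thresholds,
      ggplot2::aes(yintercept = -log10(.data$alpha_adjusted)),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  shape = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' @exportS3Method ggplot2::autoplot
autoplot.meth_correlations <- function(object, ...) {
  tbl <- as_tibble(object) |> filter(!is.na(.data$rho))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$label, y = .data$rho,
                                    colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-0.5, 0.5), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(ggplot2::vars(.data$covariate),
                        ggplot2::vars(.data$group)) +
    ggplot2::labs(x = NULL, y = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
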