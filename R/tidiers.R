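#' Tidy a deconvolution result
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return Long tibble with `sample`, `cell_type`, `proportion`.
#' @export
tidy.deconv_result <- function(x, ...) {
  tidyr::pivot_longer(x$proportions, -"sample",
                      names_to = "cell_type", values_to = "proportion")
}

#' One-row summary of a deconvolution run
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_samples`, `n_cell_types`, `n_genes`,
#'   `n_converged`, `mean_iterations`.
#' @export
glance.deconv_result <- function(x, ...) {
  tibble(
    method = x$method,
    n_samples = nrow(x$proportions),
    n_cell_types = ncol(x$proportions) - 1L,
    n_genes = length(x$gene_ids),
    n_converged = sum(x$convergence$converged),
    mean_iterations = mean(x$convergence$iterations)
  )
}

#' Plot estimated cell-type composition per sample
#'
#' @param object A `deconv_result`.
#' @param ... Unused.
#' @return A ggplot: stacked per-sample composition bars.
#' @export
autoplot.deconv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                  fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample", y = "estimated proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot estimated versus true proportions
#'
#' One panel per cell type with the identity line; points on the line are
#' perfectly concordant (CCC = 1).
#'
#' @param result A `deconv_result` or proportions table.
#' @param truth True proportions table.
#' @return A ggplot.
#' @export
plot_concordance <- function(result, truth) {
  est <- tidy_props(extract_proportions(result), "estimate")
  tru <- tidy_props(extract_proportions(truth), "truth")
  d <- dplyr::inner_join(est, tru, by = c("sample", "cell_type"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(x = "true proportion", y = "estimated proportion") +
    ggplot2::theme_minimal()
}

tidy_props <- function(p, value_name) {
  tidyr::pivot_longer(as_tibble(p), -"sample",
                      names_to = "cell_type", values_to = value_name)
}

#' Plot an evaluation report
#'
#' Per-cell-type bars of the chosen metric.
#'
#' @param object An `evaluation_report` from [evaluate_deconvolution()].
#' @param metric One of `"ccc"`, `"pearson_r"`, `"rmse"`, `"zero_fraction"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_report <- function(object, metric = "ccc", ...) {
  metric <- match.arg(metric, c("ccc", "pearson_r", "rmse", "zero_fraction"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cell_type, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cell type", y = metric) +
    ggplot2::theme_minimal()
}
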