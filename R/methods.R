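# broom-style tidiers and ggplot2 visualisations for the fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a co-expression network
#'
#' @param x A `coexpression_network` from [build_network()].
#' @param ... Unused.
#' @return One row per module: `module`, `n_genes`, `variance_explained`.
#' @export
tidy.coexpression_network <- function(x, ...) {
  ve <- attr(x$eigengenes, "variance_explained")
  ng <- attr(x$eigengenes, "n_genes")
  tibble::tibble(module = x$eigengenes$module,
                 n_genes = unname(ng[as.character(x$eigengenes$module)]),
                 variance_explained = unname(ve[as.character(x$eigengenes$module)]))
}

#' One-row network summary
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return Tibble: `n_genes`, `n_modules`, `n_unassigned`, `beta`, `type`.
#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$assignment),
                 n_modules = max(x$assignment$module),
                 n_unassigned = sum(x$assignment$module == 0),
                 beta = x$params$beta,
                 type = x$params$type)
}

#' Tidy a soft-threshold fit
#'
#' @param x A `soft_threshold_fit` from [pick_soft_threshold()].
#' @param ... Unused.
#' @return The per-power fit table with the chosen power flagged.
#' @export
tidy.soft_threshold_fit <- function(x, ...) {
  dplyr::mutate(x$fit_table, chosen = .data$power == x$beta)
}

#' Scale-free fit diagnostic plot
#'
#' R-squared of the scale-free topology fit against candidate soft powers,
#' with the selection cutoff and the chosen power marked.
#'
#' @param object A `soft_threshold_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.soft_threshold_fit <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = object$r2_cutoff, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "soft power", y = expression(R^2~"(scale-free fit)")) +
    ggplot2::theme_minimal()
}

#' Module-region association heatmap
#'
#' Tile plot of Pearson r between module eigengenes and region indicators;
#' region-specific calls are outlined.
#'
#' @param calls Called association tibble from
#'   [call_region_specific_modules()].
#' @return A ggplot.
#' @export
plot_module_trait <- function(calls) {
  calls$label <- sprintf("%.2f\n%.1e", calls$r, calls$p)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$region, y = factor(.data$module))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r), colour = "white") +
    ggplot2::geom_tile(data = calls[calls$is_region_specific, ],
                       fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "module", fill = "r") +
    ggplot2::theme_minimal()
}

#' Clustered RSG expression heatmap
#'
#' @param profile Clustered profile tibble from [rsg_expression_profile()].
#' @return A ggplot with genes in clustered order.
#' @export
plot_rsg_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, -c("gene_id", "focal_region"),
                              names_to = "sample_id", values_to = "value")
  long$gene_id <- factor(long$gene_id, levels = rev(profile$gene_id))
  long$sample_id <- factor(long$sample_id, levels = setdiff(names(profile),
                                                            c("gene_id", "focal_region")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166AC", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10(FPKM+1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}
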