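#' Relative-expression heatmap of clustered genes
#'
#' Genes are drawn in dendrogram leaf order (groups read top to bottom)
#' with a diverging palette over the clipped display range, the standard
#' rendering for diel expression groups.
#'
#' @param rel A [zscore_rows()] tibble.
#' @param clusters A [ward_cluster()] result on the same genes.
#' @param clip Display clipping bound (default 3).
#' @return A ggplot object.
#' @export
plot_heatmap <- function(rel, clusters, clip = 3) {
  labels <- setdiff(names(rel), "gene_id")
  clipped <- clip_for_display(rel, clip)
  long <- clipped |>
    tidyr::pivot_longer(dplyr::all_of(labels), names_to = "label",
                        values_to = "z") |>
    dplyr::mutate(
      label = factor(.data$label, levels = labels),
      gene_id = factor(.data$gene_id, levels = rev(clusters$leaf_order))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-clip, clip),
                                  name = "relative\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = "time point", y = "gene")
}

#' Mean profile of each expression group over the time course
#'
#' @param profiles A [group_profiles()] tibble.
#' @return A ggplot object, one facet per group.
#' @export
plot_group_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$label, y = .data$mean_z,
                               group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~group) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "time point", y = "mean relative expression")
}

#' Group-versus-genome percentage bars for overrepresented terms
#'
#' The bar-chart view of enrichment results: for each significant term,
#' the percentage of group members carrying it (dark bars) next to the
#' percentage of the background universe carrying it (grey bars).
#'
#' @param enrichment An [enrich_clusters()] (or [enrich_group()]) table.
#' @param groups Optional subset of group labels to show.
#' @return A ggplot object.
#' @export
plot_enrichment_bars <- function(enrichment, groups = NULL) {
  bars <- overrepresentation_bars(enrichment)
  if (!is.null(groups) && "group" %in% names(bars)) {
    bars <- dplyr::filter(bars, .data$group %in% groups)
  }
  long <- tidyr::pivot_longer(bars, dplyr::all_of(c("pct_in_group",
                                                    "pct_in_genome")),
                              names_to = "where", values_to = "pct") |>
    dplyr::mutate(where = ifelse(.data$where == "pct_in_group",
                                 "group", "genome"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pct, y = .data$term,
                                          fill = .data$where)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(group = "black",
                                          genome = "grey60"),
                               name = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "% of genes with term", y = NULL)
  if ("group" %in% names(bars)) {
    p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  }
  p
}

#' @describeIn plot_heatmap Heatmap autoplot for a full pipeline result.
#' @param object A `diel_pipeline` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.diel_pipeline <- function(object, ...) {
  plot_heatmap(object$relmatrix, object$clusters,
               clip = object$provenance$config$clip)
}
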