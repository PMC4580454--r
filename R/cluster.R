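#' Ward hierarchical clustering of relative expression profiles
#'
#' Agglomerative clustering of row-normalized gene profiles on Euclidean
#' distances under the Ward minimum-variance criterion, cut into `k`
#' groups. `"ward.D2"` (default) is the textbook Ward criterion with
#' squared distances inside the objective; `"ward.D"` reproduces the
#' historical behaviour of some heatmap tools. Group labels 1..k are
#' assigned in order of first appearance along the dendrogram leaf order,
#' so Group 1..k reads top-to-bottom on the heatmap.
#'
#' @param rel A [zscore_rows()] tibble.
#' @param k Number of groups to cut the tree into (study default 7).
#' @param variant Ward variant, `"ward.D2"` or `"ward.D"`.
#' @return A `diel_clusters` object: a list with `groups` (tibble
#'   `gene_id`, `group`), `hclust` (the full merge tree, whose `merge` and
#'   `height` components are the merge history), `leaf_order` (gene ids in
#'   dendrogram order) and `k`.
#' @export
ward_cluster <- function(rel, k = 7, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("k must be a positive integer")
  }
  m <- as.matrix(rel[, setdiff(names(rel), "gene_id")])
  rownames(m) <- rel$gene_id
  if (k > nrow(m)) {
    abort(paste0("k = ", k, " exceeds the number of genes (", nrow(m), ")"))
  }
  hc <- hclust(dist(m), method = variant)
  assignment <- cutree(hc, k = k)
  leaf_order <- rel$gene_id[hc$order]
  first_seen <- unique(assignment[hc$order])
  relabel <- setNames(seq_len(k), first_seen)
  groups <- tibble::tibble(
    gene_id = rel$gene_id,
    group = unname(relabel[as.character(assignment)])
  )
  structure(
    list(groups = groups, hclust = hc, leaf_order = leaf_order, k = k,
         variant = variant),
    class = "diel_clusters"
  )
}

#' @export
print.diel_clusters <- function(x, ...) {
  sizes <- table(x$groups$group)
  cat("Ward clustering (", x$variant, ") of ", nrow(x$groups),
      " genes into ", x$k, " groups\n", sep = "")
  cat("Group sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn ward_cluster Per-gene group assignments as a tibble.
#' @param x,object A `diel_clusters` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.diel_clusters <- function(x, ...) {
  x$groups
}

#' @describeIn ward_cluster One-row summary: genes, groups, merge heights.
#' @exportS3Method generics::glance
glance.diel_clusters <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$groups),
    k = x$k,
    variant = x$variant,
    min_height = min(x$hclust$height),
    max_height = max(x$hclust$height)
  )
}

#' Mean relative-expression profile of each cluster
#'
#' @param rel A [zscore_rows()] tibble.
#' @param clusters A [ward_cluster()] result covering the same genes.
#' @return A long tibble with columns `group`, `label` and `mean_z`, one
#'   row per group and time point, in design column order.
#' @export
group_profiles <- function(rel, clusters) {
  labels <- setdiff(names(rel), "gene_id")
  rel |>
    dplyr::inner_join(tidy(clusters), by = "gene_id") |>
    tidyr::pivot_longer(dplyr::all_of(labels), names_to = "label",
                        values_to = "z") |>
    dplyr::mutate(label = factor(.data$label, levels = labels)) |>
    dplyr::group_by(.data$group, .data$label) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop") |>
    dplyr::arrange(.data$group, .data$label)
}
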