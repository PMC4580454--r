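#' MeanNeighbor: mean absolute consecutive difference of a profile
#'
#' The selection statistic for diel time courses: the mean of the absolute
#' differences between expression values at consecutive time points,
#' `mean(|x[t+1] - x[t]|)` over the `T - 1` gaps of the collection order.
#' There is no wraparound term between the last and first time point.
#' Because the differences are in FPKM units, the score is large only for
#' genes that are both highly expressed and temporally variable, which is
#' exactly the joint criterion it is used to impose.
#'
#' @param x Numeric vector of length ≥ 2: one gene's profile in design
#'   (collection) order.
#' @return A single non-negative number in FPKM units.
#' @examples
#' mean_neighbor(c(1, 3, 2, 5, 5, 5, 4)) # 7/6
#' @export
mean_neighbor <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    abort("mean_neighbor requires a numeric profile of length ≥ 2")
  }
  if (any(!is.finite(x))) {
    abort("mean_neighbor requires finite values")
  }
  mean(abs(diff(x)))
}

#' Score every gene of an expression matrix by MeanNeighbor
#'
#' Ranks are assigned by descending score; ties are broken by ascending
#' lexicographic `gene_id` so that selection is deterministic.
#'
#' @param expr Expression tibble (`gene_id` + one column per design label).
#' @param design A design tibble.
#' @return A tibble with columns `gene_id`, `score`, `rank`, sorted by
#'   rank.
#' @export
score_genes <- function(expr, design) {
  design <- validate_design(design)
  expr <- validate_expression(expr, design)
  vals <- as.matrix(expr[, design$label])
  score <- rowMeans(abs(vals[, -1, drop = FALSE] -
                          vals[, -ncol(vals), drop = FALSE]))
  tibble::tibble(gene_id = expr$gene_id, score = unname(score)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Select the top-n genes by MeanNeighbor rank
#'
#' @param scores A [score_genes()] table.
#' @param n Number of genes to keep (the study default is 1000). When `n`
#'   exceeds the number of scored genes, all genes are returned.
#' @return Character vector of gene ids in rank order, length `min(n, G)`.
#' @export
select_top_n <- function(scores, n = 1000) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort("n must be a positive integer")
  }
  scores <- dplyr::arrange(scores, .data$rank)
  head(scores$gene_id, n)
}
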