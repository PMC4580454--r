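#' Normalize gene profiles to relative expression (row z-scores)
#'
#' Each gene's FPKM profile is centred on its own mean across the time
#' course and divided by its sample standard deviation (denominator
#' `T - 1`), giving a dimensionless relative expression level per time
#' point. Genes with zero variance across the time course carry no
#' temporal signal and cannot be z-scored; they are excluded with a
#' warning and reported in the `"excluded"` attribute of the result.
#'
#' @param expr Expression tibble (`gene_id` + one column per design label).
#' @param design A design tibble.
#' @return A tibble of the same shape restricted to non-constant genes,
#'   each row with mean 0 and sample sd 1; attribute `excluded` holds the
#'   gene ids of any zero-variance rows.
#' @examples
#' d <- diel_design(c("D6", "L1", "L10"))
#' zscore_rows(tibble::tibble(gene_id = "g1", D6 = 1, L1 = 2, L10 = 3), d)
#' @export
zscore_rows <- function(expr, design) {
  design <- validate_design(design)
  expr <- validate_expression(expr, design)
  vals <- as.matrix(expr[, design$label])
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, sd)
  constant <- sdv == 0
  excluded <- expr$gene_id[constant]
  if (length(excluded) > 0) {
    warn(paste0(length(excluded), " zero-variance gene(s) excluded from ",
                "normalization: ",
                paste(head(excluded, 5), collapse = ", "),
                if (length(excluded) > 5) ", ..." else ""))
  }
  z <- (vals[!constant, , drop = FALSE] - mu[!constant]) / sdv[!constant]
  rel <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = expr$gene_id[!constant]),
    tibble::as_tibble(z)
  ))
  attr(rel, "excluded") <- excluded
  rel
}

#' Clip relative expression for heatmap display
#'
#' Limits z-scores to `[-bound, +bound]` (default 3, the conventional
#' display range for relative expression heatmaps). Clipping is used only
#' for rendering; clustering and enrichment always operate on unclipped
#' values. For a 7-point time course the maximum attainable |z| under the
#' sample-sd convention is about 2.27, so the default bound is in fact
#' vacuous there; it matters for longer designs.
#'
#' @param rel A [zscore_rows()] tibble.
#' @param bound Positive clipping bound.
#' @return A tibble of identical shape with values in `[-bound, bound]`.
#' @export
clip_for_display <- function(rel, bound = 3) {
  if (!is.numeric(bound) || length(bound) != 1 || bound <= 0) {
    abort("bound must be a positive number")
  }
  dplyr::mutate(rel, dplyr::across(dplyr::where(is.numeric),
                                   ~ pmin(pmax(.x, -bound), bound)))
}
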