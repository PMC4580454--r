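#' Run the full diel expression analysis pipeline
#'
#' Executes the stages in study order: MeanNeighbor scoring, top-n
#' selection, per-gene z-score normalization (zero-variance genes excluded
#' with a warning), Ward clustering into `k` groups, per-group GO-term
#' overrepresentation with the adaptive cutoff, and per-gene temporal
#' pattern characterization. The pipeline itself is deterministic: given
#' identical inputs and configuration it produces identical results; the
#' `seed` argument is only echoed into provenance so a simulation seed can
#' travel with its results.
#'
#' @param expr Expression tibble (`gene_id` + one column per design
#'   label), FPKM units.
#' @param annotations Annotation tibble (`gene_id`, `term`); may be
#'   missing genes present in `expr` (they count as unannotated).
#' @param design A design tibble.
#' @param top_n Number of genes to select (study default 1000).
#' @param k Number of expression groups (study default 7).
#' @param ward_variant `"ward.D2"` or `"ward.D"`.
#' @param clip Display clipping bound for the heatmap (default 3).
#' @param alpha,overflow_threshold,strict_alpha Enrichment cutoff policy;
#'   see [enrich_group()].
#' @param background Background universe convention: `"all"` (every gene
#'   in the expression table, default) or `"annotated"` (only genes with
#'   at least one annotation).
#' @param fdr Benjamini-Hochberg adjust enrichment p-values.
#' @param pseudocount,min_fold Pattern parameters; see
#'   [classify_pattern()].
#' @param seed Optional integer echoed into provenance.
#' @return A `diel_pipeline` object: list with `scores`, `selected`,
#'   `relmatrix`, `clusters`, `enrichment`, `patterns`, `profiles` and
#'   `provenance`.
#' @export
run_pipeline <- function(expr, annotations, design, top_n = 1000, k = 7,
                         ward_variant = c("ward.D2", "ward.D"), clip = 3,
                         alpha = 0.05, overflow_threshold = 100,
                         strict_alpha = 1e-7,
                         background = c("all", "annotated"), fdr = FALSE,
                         pseudocount = 0.01, min_fold = 2, seed = NULL) {
  ward_variant <- match.arg(ward_variant)
  background <- match.arg(background)
  if (top_n < k || k < 1) {
    abort("configuration invalid: need top_n >= k >= 1")
  }
  design <- validate_design(design)
  expr <- validate_expression(expr, design)

  scores <- score_genes(expr, design)
  selected <- select_top_n(scores, top_n)
  sel_expr <- expr[match(selected, expr$gene_id), ]
  rel <- zscore_rows(sel_expr, design)
  excluded <- attr(rel, "excluded")
  if (k > nrow(rel)) {
    abort(paste0("clustering: k = ", k, " exceeds the ", nrow(rel),
                 " selected genes remaining after zero-variance exclusion"))
  }
  clusters <- ward_cluster(rel, k = k, variant = ward_variant)
  universe <- switch(background,
    all = expr$gene_id,
    annotated = intersect(expr$gene_id, unique(annotations$gene_id))
  )
  enrichment <- enrich_clusters(clusters, annotations, universe,
                                alpha = alpha,
                                overflow_threshold = overflow_threshold,
                                strict_alpha = strict_alpha, fdr = fdr)
  patterns <- characterize_patterns(sel_expr, design, min_fold = min_fold,
                                    pseudocount = pseudocount)
  cutoff_applied <- lapply(seq_len(k), function(g) {
    rows <- enrichment$group == g
    if (any(rows)) enrichment$cutoff_applied[rows][1] else alpha
  })
  names(cutoff_applied) <- as.character(seq_len(k))
  provenance <- list(
    config = list(top_n = top_n, k = k, ward_variant = ward_variant,
                  clip = clip, alpha = alpha,
                  overflow_threshold = overflow_threshold,
                  strict_alpha = strict_alpha, background = background,
                  fdr = fdr, pseudocount = pseudocount,
                  min_fold = min_fold),
    seed = seed,
    counts = list(genes_in = nrow(expr), selected = length(selected),
                  excluded = length(excluded),
                  clustered = nrow(rel),
                  terms_tested = nrow(enrichment),
                  significant = sum(enrichment$significant)),
    excluded_genes = excluded,
    cutoff_applied = cutoff_applied,
    design = design
  )
  structure(
    list(scores = scores, selected = selected, relmatrix = rel,
         clusters = clusters, enrichment = enrichment, patterns = patterns,
         profiles = group_profiles(rel, clusters),
         provenance = provenance),
    class = "diel_pipeline"
  )
}

#' @export
print.diel_pipeline <- function(x, ...) {
  cnt <- x$provenance$counts
  cat("Diel expression pipeline result\n")
  cat("  genes in:        ", cnt$genes_in, "\n")
  cat("  selected (top-n):", cnt$selected, "\n")
  cat("  clustered:       ", cnt$clustered, " in ", x$clusters$k,
      " groups\n", sep = "")
  cat("  terms tested:    ", cnt$terms_tested,
      " (", cnt$significant, " significant)\n", sep = "")
  invisible(x)
}

#' Tidy a pipeline result into one row per selected gene
#'
#' Joins the MeanNeighbor score and rank, group assignment and temporal
#' pattern of every clustered gene.
#'
#' @param x A `diel_pipeline` object.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `score`, `rank`, `group`,
#'   `peak`, `trough`, `max_fpkm`, `fold_change`, `pattern_class`.
#' @exportS3Method generics::tidy
tidy.diel_pipeline <- function(x, ...) {
  tidy(x$clusters) |>
    dplyr::left_join(x$scores, by = "gene_id") |>
    dplyr::left_join(x$patterns, by = "gene_id") |>
    dplyr::select(dplyr::all_of(c("gene_id", "score", "rank", "group",
                                  "peak", "trough", "max_fpkm",
                                  "fold_change", "pattern_class"))) |>
    dplyr::arrange(.data$rank)
}

#' One-row summary of a pipeline result
#'
#' @param x A `diel_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble: gene counts per stage, group count and
#'   significant-term count.
#' @exportS3Method generics::glance
glance.diel_pipeline <- function(x, ...) {
  cnt <- x$provenance$counts
  tibble::tibble(
    n_genes = cnt$genes_in,
    n_selected = cnt$selected,
    n_excluded = cnt$excluded,
    n_clustered = cnt$clustered,
    k = x$clusters$k,
    n_terms_tested = cnt$terms_tested,
    n_significant = cnt$significant
  )
}
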