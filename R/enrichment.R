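#' 2x2 contingency counts for one group and one GO term
#'
#' Counts against a stated background universe: `a` group members carrying
#' the term, `b` group members without it, `c` background (non-group)
#' genes with the term, `d` background genes without it. Genes in the
#' universe that carry no annotation at all contribute to `b`/`d`, which
#' is the norm in draft-genome annotations where many genes have no
#' homolog.
#'
#' @param group_genes Character vector of gene ids; must be a subset of
#'   `universe`.
#' @param term A single GO term identifier (an opaque label).
#' @param annotations Annotation tibble (`gene_id`, `term`).
#' @param universe Character vector of background gene ids.
#' @return A one-row tibble with integer columns `a`, `b`, `c`, `d`.
#' @export
contingency_counts <- function(group_genes, term, annotations, universe) {
  group_genes <- unique(group_genes)
  universe <- unique(universe)
  outside <- setdiff(group_genes, universe)
  if (length(outside) > 0) {
    abort(paste0("group gene outside universe: ", outside[1]))
  }
  term_genes <- intersect(
    unique(annotations$gene_id[annotations$term == term]), universe)
  a <- length(intersect(group_genes, term_genes))
  b <- length(group_genes) - a
  c <- length(term_genes) - a
  d <- length(universe) - length(group_genes) - c
  tibble::tibble(a = a, b = b, c = c, d = d)
}

#' One-sided Fisher's exact p-value for overrepresentation
#'
#' The p-value of observing at least `a` term-carrying genes in the group
#' under the hypergeometric null fixed by the table margins,
#' `P(X >= a)`. Computed exactly via the hypergeometric tail (log-space
#' internally), so large universes are handled without underflow. A
#' two-sided alternative is available for completeness.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized for the
#'   one-sided case).
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"`.
#' @return Numeric p-value(s) in `[0, 1]`.
#' @examples
#' fisher_overrep_p(2, 0, 0, 2) # 1/6
#' @export
fisher_overrep_p <- function(a, b, c, d,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) {
    abort("contingency counts must be non-negative")
  }
  if (alternative == "greater") {
    # X ~ Hypergeom(white = a + c, black = b + d, drawn = a + b)
    phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  } else {
    mapply(function(a, b, c, d) {
      fisher.test(matrix(c(a, c, b, d), nrow = 2),
                  alternative = "two.sided")$p.value
    }, a, b, c, d)
  }
}

#' GO-term overrepresentation for one gene group
#'
#' Tests every term annotated to at least one group member with the
#' one-sided Fisher's exact test against the background universe.
#' Significance is first assessed at `alpha` (study default 0.05); if the
#' number of significant terms exceeds `overflow_threshold` (default 100),
#' significance is re-assessed at `strict_alpha` (default 1e-7) and the
#' applied cutoff is recorded — the adaptive rule used in the study for
#' its largest expression group. Records are sorted by ascending p-value,
#' ties by term id.
#'
#' @inheritParams contingency_counts
#' @param alpha Primary p-value cutoff.
#' @param overflow_threshold Maximum number of significant terms tolerated
#'   before switching to `strict_alpha`.
#' @param strict_alpha Stricter cutoff applied on overflow.
#' @param alternative Passed to [fisher_overrep_p()].
#' @param fdr If `TRUE`, p-values are Benjamini-Hochberg adjusted (column
#'   `p_adjusted`) and significance is assessed on the adjusted values.
#' @return A tibble with one row per tested term: `term`, `a`, `b`, `c`,
#'   `d`, `p_value`, `pct_in_group`, `pct_in_genome`, `significant`,
#'   `cutoff_applied` (plus `p_adjusted` when `fdr = TRUE`).
#' @export
enrich_group <- function(group_genes, annotations, universe,
                         alpha = 0.05, overflow_threshold = 100,
                         strict_alpha = 1e-7,
                         alternative = c("greater", "two.sided"),
                         fdr = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(strict_alpha < alpha, overflow_threshold >= 1)
  group_genes <- unique(group_genes)
  universe <- unique(universe)
  if (length(group_genes) == 0) {
    abort("group must be non-empty")
  }
  outside <- setdiff(group_genes, universe)
  if (length(outside) > 0) {
    abort(paste0("group gene outside universe: ", outside[1]))
  }
  ann <- dplyr::distinct(annotations[annotations$gene_id %in% universe, ])
  terms <- sort(unique(ann$term[ann$gene_id %in% group_genes]))
  empty <- tibble::tibble(
    term = character(), a = integer(), b = integer(), c = integer(),
    d = integer(), p_value = double(), pct_in_group = double(),
    pct_in_genome = double(), significant = logical(),
    cutoff_applied = double()
  )
  if (length(terms) == 0) {
    return(empty)
  }
  n_univ <- length(universe)
  n_grp <- length(group_genes)
  term_total <- table(factor(ann$term, levels = terms))
  in_group <- table(factor(ann$term[ann$gene_id %in% group_genes],
                           levels = terms))
  a <- as.integer(in_group)
  tot <- as.integer(term_total)
  b <- n_grp - a
  c <- tot - a
  d <- n_univ - n_grp - c
  p <- fisher_overrep_p(a, b, c, d, alternative = alternative)
  rec <- tibble::tibble(
    term = terms, a = a, b = b, c = c, d = d, p_value = p,
    pct_in_group = 100 * a / n_grp,
    pct_in_genome = 100 * tot / n_univ
  )
  crit <- rec$p_value
  if (fdr) {
    rec$p_adjusted <- p.adjust(rec$p_value, method = "BH")
    crit <- rec$p_adjusted
  }
  cutoff <- alpha
  if (sum(crit <= cutoff) > overflow_threshold) {
    cutoff <- strict_alpha
  }
  rec$significant <- crit <= cutoff
  rec$cutoff_applied <- cutoff
  dplyr::arrange(rec, .data$p_value, .data$term)
}

#' GO-term overrepresentation for every cluster
#'
#' Applies [enrich_group()] to each group of a clustering, against a
#' shared background universe.
#'
#' @param clusters A [ward_cluster()] result.
#' @inheritParams enrich_group
#' @return A tibble of per-term records with a leading `group` column.
#' @export
enrich_clusters <- function(clusters, annotations, universe,
                            alpha = 0.05, overflow_threshold = 100,
                            strict_alpha = 1e-7,
                            alternative = c("greater", "two.sided"),
                            fdr = FALSE) {
  alternative <- match.arg(alternative)
  groups <- tidy(clusters)
  universe <- unique(universe)
  purrr::map_dfr(seq_len(clusters$k), function(g) {
    # members outside the chosen universe (e.g. unannotated genes under the
    # annotated-only background) cannot enter the contingency table
    members <- intersect(groups$gene_id[groups$group == g], universe)
    if (length(members) == 0) {
      return(tibble::tibble())
    }
    rec <- enrich_group(members, annotations, universe, alpha = alpha,
                        overflow_threshold = overflow_threshold,
                        strict_alpha = strict_alpha,
                        alternative = alternative, fdr = fdr)
    dplyr::bind_cols(tibble::tibble(group = rep(g, nrow(rec))), rec)
  })
}

#' Percentage bars for significant terms
#'
#' The classic group-versus-genome bar chart data: for each significant
#' term, the percentage of group members carrying the term next to the
#' percentage of the background universe carrying it.
#'
#' @param records An [enrich_group()] (or one group of an
#'   [enrich_clusters()]) table.
#' @return A tibble with columns `term`, `pct_in_group`, `pct_in_genome`,
#'   significant records only, in ascending p-value order.
#' @export
overrepresentation_bars <- function(records) {
  records |>
    dplyr::filter(.data$significant) |>
    dplyr::select(dplyr::any_of(c("group", "term", "pct_in_group",
                                  "pct_in_genome")))
}
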