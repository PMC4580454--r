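#' Read a gene-by-time FPKM expression table
#'
#' The file must be tab-separated with a header, a first column `gene_id`
#' and one column per design label. Columns may appear in any order in the
#' file; they are reordered to the design's collection order. Values must
#' be finite, non-negative reals (FPKM units).
#'
#' @param path Path to a TSV file.
#' @param design A design tibble (see [diel_design()]).
#' @return A tibble with columns `gene_id` followed by one numeric column
#'   per design label, in design order.
#' @export
read_expression_table <- function(path, design) {
  design <- validate_design(design)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(raw)[1] != "gene_id") {
    abort("expression table must have 'gene_id' as its first column")
  }
  missing <- setdiff(design$label, names(raw))
  if (length(missing) > 0) {
    abort(paste0("expression table lacks design column(s): ",
                 paste(missing, collapse = ", ")))
  }
  expr <- raw[, c("gene_id", design$label)]
  for (lab in design$label) {
    parsed <- suppressWarnings(as.numeric(expr[[lab]]))
    bad <- which(is.na(parsed) | !is.finite(parsed))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value for gene ", expr$gene_id[bad[1]],
                   " in column ", lab))
    }
    neg <- which(parsed < 0)
    if (length(neg) > 0) {
      abort(paste0("negative FPKM value for gene ", expr$gene_id[neg[1]],
                   " in column ", lab))
    }
    expr[[lab]] <- parsed
  }
  validate_expression(expr, design)
}

validate_expression <- function(expr, design) {
  design <- validate_design(design)
  if (!is.data.frame(expr) || names(expr)[1] != "gene_id") {
    abort("expression table must have 'gene_id' as its first column")
  }
  missing <- setdiff(design$label, names(expr))
  if (length(missing) > 0) {
    abort(paste0("expression table lacks design column(s): ",
                 paste(missing, collapse = ", ")))
  }
  expr <- tibble::as_tibble(expr)[, c("gene_id", design$label)]
  dup <- expr$gene_id[duplicated(expr$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id: ", dup[1]))
  }
  vals <- as.matrix(expr[, design$label])
  if (any(!is.finite(vals))) {
    abort("expression values must be finite")
  }
  if (any(vals < 0)) {
    gi <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(paste0("negative FPKM value for gene ", expr$gene_id[gi[1]],
                 " in column ", design$label[gi[2]]))
  }
  expr
}

#' Write an expression (or relative-expression) table
#'
#' Numeric values are written with 6 significant digits, below biological
#' meaning for FPKM but above test tolerance, so that a write/read round
#' trip preserves values at the declared precision.
#'
#' @param expr A tibble with `gene_id` plus numeric time-point columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  out <- dplyr::mutate(expr, dplyr::across(dplyr::where(is.numeric),
                                           ~ signif(.x, 6)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene-to-GO annotation table
#'
#' Expects a two-column tab-separated file with header `gene_id`, `term`.
#' Duplicate (gene, term) pairs collapse to one. The distinct gene ids seen
#' form the annotation universe; genes absent from the file simply carry no
#' terms.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id` and `term`, one row per distinct
#'   pair.
#' @export
read_annotation_table <- function(path) {
  n_fields <- readr::count_fields(path, readr::tokenizer_tsv())
  bad <- which(n_fields != 2)
  if (length(bad) > 0) {
    abort(paste0("annotation file line ", bad[1], " has ", n_fields[bad[1]],
                 " fields; expected 2 (gene_id, term)"))
  }
  ann <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (nrow(ann) == 0 && ncol(ann) < 2) {
    return(tibble::tibble(gene_id = character(), term = character()))
  }
  names(ann) <- c("gene_id", "term")
  dplyr::distinct(ann)
}

#' Read a GAF 2.x annotation file
#'
#' A minimal reader for Gene Ontology GAF 2.x: comment lines starting with
#' `!` are skipped and only column 2 (object identifier) and column 5 (GO
#' identifier) are used; qualifiers and evidence codes are ignored.
#'
#' @param path Path to a GAF file.
#' @return A tibble with columns `gene_id` and `term`.
#' @export
read_gaf <- function(path) {
  gaf <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(gaf) == 0) {
    return(tibble::tibble(gene_id = character(), term = character()))
  }
  if (ncol(gaf) < 5) {
    abort("GAF file must have at least 5 tab-separated columns")
  }
  dplyr::distinct(tibble::tibble(gene_id = gaf[[2]], term = gaf[[5]]))
}

#' Write a full pipeline result to a directory
#'
#' Writes the seven standard output files: `scores.tsv`, `selected.tsv`,
#' `relmatrix.tsv`, `clusters.tsv`, `enrichment.tsv`, `patterns.tsv` and
#' `summary.json`. All tables carry headers; the JSON summary records the
#' configuration echo, group sizes, per-group significant-term counts and
#' the enrichment cutoff applied to each group. Output contains no
#' timestamps, so re-running on the same result is byte-identical.
#'
#' @param result A [run_pipeline()] result.
#' @param outdir Output directory; created if absent.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "diel_pipeline"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) {
    abort(paste0("cannot create output directory ", outdir))
  }
  paths <- file.path(outdir, c("scores.tsv", "selected.tsv", "relmatrix.tsv",
                               "clusters.tsv", "enrichment.tsv",
                               "patterns.tsv", "summary.json"))
  readr::write_tsv(result$scores, paths[1])
  readr::write_tsv(tibble::tibble(gene_id = result$selected,
                                  rank = seq_along(result$selected)),
                   paths[2])
  write_expression_table(result$relmatrix, paths[3])
  readr::write_tsv(tidy(result$clusters), paths[4])
  readr::write_tsv(result$enrichment, paths[5])
  readr::write_tsv(result$patterns, paths[6])
  groups <- tidy(result$clusters)
  group_sizes <- as.list(table(groups$group))
  sig <- dplyr::filter(result$enrichment, .data$significant)
  sig_counts <- lapply(seq_len(result$clusters$k), function(g) {
    sum(sig$group == g)
  })
  names(sig_counts) <- as.character(seq_len(result$clusters$k))
  summary <- list(
    n_genes = result$provenance$counts$genes_in,
    n_selected = length(result$selected),
    n_excluded_zero_variance = result$provenance$counts$excluded,
    k = result$clusters$k,
    group_sizes = group_sizes,
    significant_terms = sig_counts,
    cutoff_applied = result$provenance$cutoff_applied,
    config = result$provenance$config,
    seed = result$provenance$seed
  )
  jsonlite::write_json(summary, paths[7], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
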