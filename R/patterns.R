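# internal single-profile primitives; callers have validated the design
peak_label <- function(x, labels) labels[which.max(x)]
trough_label <- function(x, labels) labels[which.min(x)]

fold_change_impl <- function(x, pseudocount) {
  lo <- min(x)
  if (lo + pseudocount == 0) {
    abort("zero trough requires pseudocount")
  }
  (max(x) + pseudocount) / (lo + pseudocount)
}

classify_impl <- function(x, labels, min_fold, pseudocount) {
  peak <- peak_label(x, labels)
  fc <- fold_change_impl(x, pseudocount)
  if (peak %in% c("D10", "L1") && fc >= min_fold) {
    return("dark_to_dawn_peak")
  }
  late_light <- intersect(c("L4", "L6", "L10"), labels)
  if (peak %in% late_light && fc >= min_fold) {
    ramp <- x[match("L4", labels):match(peak, labels)]
    if (sum(diff(ramp) < 0) <= 1) {
      return("late_light_peak")
    }
  }
  "other"
}

check_pattern_labels <- function(design) {
  missing <- setdiff(c("D10", "L1", "L4", "L10"), design$label)
  if (length(missing) > 0) {
    abort(paste0("design lacks required label(s) for pattern ",
                 "classification: ", paste(missing, collapse = ", ")))
  }
}

#' Peak and trough time of a profile
#'
#' Returns the design label at which a profile attains its maximum
#' (`peak_time`) or minimum (`trough_time`). Ties resolve to the earliest
#' tied time point in collection order.
#'
#' @param x Numeric profile in design order.
#' @param design A design tibble.
#' @return A single time-point label.
#' @export
peak_time <- function(x, design) {
  design <- validate_design(design)
  if (length(x) != nrow(design)) {
    abort("profile length must equal the number of design time points")
  }
  peak_label(x, design$label)
}

#' @rdname peak_time
#' @export
trough_time <- function(x, design) {
  design <- validate_design(design)
  if (length(x) != nrow(design)) {
    abort("profile length must equal the number of design time points")
  }
  trough_label(x, design$label)
}

#' Fold change of a profile over its lowest value
#'
#' `(max + pseudocount) / (min + pseudocount)`. The pseudocount (default
#' 0.01 FPKM) keeps the ratio defined at zero troughs; it is negligible
#' against typical FPKM scales (tens to thousands).
#'
#' @param x Numeric profile (non-negative FPKM values).
#' @param pseudocount Non-negative value added to numerator and
#'   denominator.
#' @return A number ≥ 1.
#' @export
fold_change <- function(x, pseudocount = 0.01) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount < 0) {
    abort("pseudocount must be a non-negative number")
  }
  fold_change_impl(x, pseudocount)
}

#' Classify a temporal expression pattern
#'
#' Distinguishes the two diel shapes described for fatty-acid pathway
#' transcripts in haptophyte time courses:
#' * `dark_to_dawn_peak` — expression peaking at the dark-to-dawn
#'   transition (peak at D10 or L1) with at least `min_fold` change; the
#'   shape of plastid-localized fatty-acid synthesis genes.
#' * `late_light_peak` — a gradual rise through the light phase, peaking
#'   at L4, L6 or L10 with at least `min_fold` change and a non-decreasing
#'   profile from L4 through the peak (one single-step violation
#'   tolerated); the shape of ER-associated TAG-assembly genes.
#' * `other` — anything else, including flat profiles below the fold gate.
#'
#' @param x Numeric profile in design order.
#' @param design A design tibble; must contain labels D10, L1, L4 and L10.
#' @param min_fold Minimum fold change to call either class (default 2,
#'   the lower end of the reported ER-pathway range).
#' @param pseudocount Passed to [fold_change()].
#' @return One of `"dark_to_dawn_peak"`, `"late_light_peak"`, `"other"`.
#' @export
classify_pattern <- function(x, design, min_fold = 2, pseudocount = 0.01) {
  design <- validate_design(design)
  check_pattern_labels(design)
  classify_impl(x, design$label, min_fold, pseudocount)
}

#' Characterize the temporal pattern of every gene
#'
#' Per-gene peak time, trough time, maximum FPKM, fold change over the
#' lowest value and pattern class, computed on the raw (unnormalized)
#' profiles.
#'
#' @param expr Expression tibble (`gene_id` + one column per design
#'   label).
#' @param design A design tibble.
#' @inheritParams classify_pattern
#' @return A tibble with columns `gene_id`, `peak`, `trough`, `max_fpkm`,
#'   `fold_change`, `pattern_class`.
#' @export
characterize_patterns <- function(expr, design, min_fold = 2,
                                  pseudocount = 0.01) {
  design <- validate_design(design)
  check_pattern_labels(design)
  expr <- validate_expression(expr, design)
  vals <- as.matrix(expr[, design$label])
  labels <- design$label
  tibble::tibble(
    gene_id = expr$gene_id,
    peak = labels[max.col(vals, ties.method = "first")],
    trough = labels[max.col(-vals, ties.method = "first")],
    max_fpkm = apply(vals, 1, max),
    fold_change = apply(vals, 1, fold_change_impl, pseudocount),
    pattern_class = apply(vals, 1, classify_impl, labels, min_fold,
                          pseudocount)
  )
}
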