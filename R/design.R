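#' Time-course designs
#'
#' A design names the ordered collection time points of a diel (light/dark)
#' expression time course. Each point has a short `label` (e.g. `"L4"` for
#' hour 4 of the light phase), a `phase` (`"light"` or `"dark"`) and an
#' `hour` within that phase. The row order is the experimental collection
#' order; every downstream profile operation (consecutive differences, peak
#' calling, ramp detection) follows it.
#'
#' `diel_design()` builds the default 7-point design used throughout the
#' package: samples at dark hours 6 and 10, light hours 1, 4, 6 and 10, and
#' dark hour 1 of the following night, in that collection order.
#'
#' @param labels Character vector of unique time-point labels of the form
#'   `"D<hour>"` or `"L<hour>"`.
#' @return A tibble with columns `label`, `phase`, `hour`, one row per time
#'   point in collection order.
#' @examples
#' diel_design()
#' @export
diel_design <- function(labels = c("D6", "D10", "L1", "L4", "L6", "L10", "D1")) {
  phase <- ifelse(startsWith(labels, "D"), "dark", "light")
  hour <- suppressWarnings(as.integer(sub("^[DL]", "", labels)))
  design <- tibble::tibble(label = labels, phase = phase, hour = hour)
  validate_design(design)
}

validate_design <- function(design) {
  if (!is.data.frame(design) ||
      !all(c("label", "phase", "hour") %in% names(design))) {
    abort("design must be a data frame with columns label, phase, hour")
  }
  design <- tibble::as_tibble(design)
  design$phase <- tolower(design$phase)
  if (nrow(design) < 2) {
    abort("design must have ≥ 2 time points")
  }
  if (anyNA(design$label) || any(!nzchar(design$label))) {
    abort("design labels must be non-empty")
  }
  dup <- design$label[duplicated(design$label)]
  if (length(dup) > 0) {
    abort(paste0("duplicate design label: ", dup[1]))
  }
  bad <- setdiff(unique(design$phase), c("light", "dark"))
  if (length(bad) > 0) {
    row <- which(design$phase == bad[1])[1]
    abort(paste0("unknown phase '", bad[1], "' in design row ", row,
                 " (label ", design$label[row], "); expected light or dark"))
  }
  if (anyNA(design$hour) || any(design$hour < 0)) {
    row <- which(is.na(design$hour) | design$hour < 0)[1]
    abort(paste0("hour must be a non-negative integer; offending row ", row,
                 " (label ", design$label[row], ")"))
  }
  design$hour <- as.integer(design$hour)
  design
}

#' Read a time-course design file
#'
#' Reads a tab-separated design table with header columns `label`, `phase`
#' and `hour`. File row order is authoritative: it defines the collection
#' order used by all downstream operations. Phase tokens are normalized to
#' lower case.
#'
#' @param path Path to a TSV file.
#' @return A design tibble (see [diel_design()]).
#' @export
read_design <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(
    label = readr::col_character(),
    phase = readr::col_character(),
    hour = readr::col_integer()
  ), progress = FALSE)
  missing <- setdiff(c("label", "phase", "hour"), names(design))
  if (length(missing) > 0) {
    abort(paste0("design file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  validate_design(design[, c("label", "phase", "hour")])
}

#' Write a design table
#'
#' @param design A design tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(validate_design(design), path)
  invisible(path)
}
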