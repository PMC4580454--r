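#' Template shapes for simulated expression groups
#'
#' Deterministic unit-variance templates over a design: one single-peak
#' template per time point (a spike at that point, z-scored), followed by
#' a rising and a falling linear ramp for group counts exceeding the
#' number of time points. Deterministic templates make the designed
#' pattern class of every simulated gene exact.
#'
#' @param design A design tibble.
#' @param k Number of templates needed.
#' @return A `k` x `T` numeric matrix; each row has mean 0, sample sd 1.
#' @export
group_templates <- function(design, k) {
  design <- validate_design(design)
  t_n <- nrow(design)
  max_k <- t_n + 2
  if (k > max_k) {
    abort(paste0("k = ", k, " exceeds the ", max_k,
                 " available templates for a ", t_n, "-point design"))
  }
  zscore <- function(v) (v - mean(v)) / sd(v)
  shapes <- lapply(seq_len(min(k, t_n)), function(t) {
    zscore(as.numeric(seq_len(t_n) == t))
  })
  if (k > t_n) {
    ramps <- list(zscore(seq_len(t_n)), zscore(rev(seq_len(t_n))))
    shapes <- c(shapes, ramps[seq_len(k - t_n)])
  }
  m <- do.call(rbind, shapes)
  colnames(m) <- design$label
  m
}

template_pattern_class <- function(template, design) {
  peak <- design$label[which.max(template)]
  if (peak %in% c("D10", "L1")) {
    return("dark_to_dawn_peak")
  }
  late <- intersect(c("L4", "L6", "L10"), design$label)
  if (peak %in% late) {
    i_l4 <- match("L4", design$label)
    i_peak <- match(peak, design$label)
    if (all(diff(template[i_l4:i_peak]) >= 0)) {
      return("late_light_peak")
    }
  }
  "other"
}

planted_term_id <- function(group) {
  sprintf("GO:P%06d", group)
}

#' Simulate an FPKM time course with known group structure
#'
#' Generates `n_groups * genes_per_group` grouped genes plus
#' `n_background` flat background genes over a diel design. Gene `i` of
#' group `g` has `FPKM_t = b_i * exp(amplitude * z_g(t) + e_it)` with the
#' group template `z_g` from [group_templates()], log-normal baselines
#' `b_i` and Gaussian noise `e_it` on the log scale (multiplicative on
#' FPKM, keeping values strictly positive and scale-heterogeneous across
#' genes, as real FPKM tables are). Background genes have amplitude 0.
#' Fully reproducible from `seed`.
#'
#' Defaults emulate the study conditions: the 7-point diel design, 7
#' temporally distinct groups of 100 genes within a roughly 5000-gene
#' transcriptome, baselines around 50 FPKM spanning orders of magnitude,
#' and within-gene noise small relative to the group signal.
#'
#' @param design A design tibble.
#' @param n_groups Number of expression groups (templates).
#' @param genes_per_group Genes per group.
#' @param n_background Flat background genes.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline
#'   parameters (natural log; defaults `log(50)` and 1).
#' @param amplitude Template amplitude on the log scale, as a multiple of
#'   the unit-variance template (default 0.8).
#' @param noise_sd Log-scale noise sd (default 0.2).
#' @param seed Integer seed; required for reproducibility.
#' @return A list with `expression` (tibble `gene_id` + design labels) and
#'   `truth` (tibble `gene_id`, `group` — `"background"` or `"1"`..`"k"` —,
#'   `planted_term`, `pattern_class`).
#' @export
simulate_timecourse <- function(design = diel_design(), n_groups = 7,
                                genes_per_group = 100, n_background = 4300,
                                baseline_log_mean = log(50),
                                baseline_log_sd = 1, amplitude = 0.8,
                                noise_sd = 0.2, seed = 1) {
  design <- validate_design(design)
  stopifnot(n_groups >= 1, genes_per_group >= 0, n_background >= 0,
            noise_sd >= 0, amplitude >= 0)
  set.seed(seed)
  t_n <- nrow(design)
  templates <- group_templates(design, n_groups)
  n_grouped <- n_groups * genes_per_group
  n <- n_grouped + n_background
  group <- c(rep(seq_len(n_groups), each = genes_per_group),
             rep(NA_integer_, n_background))
  gene_id <- sprintf("gene%05d", seq_len(n))
  baseline <- rlnorm(n, meanlog = baseline_log_mean, sdlog = baseline_log_sd)
  z <- matrix(0, nrow = n, ncol = t_n)
  if (n_grouped > 0) {
    z[seq_len(n_grouped), ] <- templates[group[seq_len(n_grouped)], ,
                                         drop = FALSE]
  }
  eps <- matrix(rnorm(n * t_n, mean = 0, sd = noise_sd), nrow = n)
  fpkm <- baseline * exp(amplitude * z + eps)
  colnames(fpkm) <- design$label
  expression <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id),
                                 tibble::as_tibble(fpkm))
  class_of_group <- vapply(seq_len(n_groups), function(g) {
    template_pattern_class(templates[g, ], design)
  }, character(1))
  grouped <- !is.na(group)
  planted_term <- rep(NA_character_, n)
  planted_term[grouped] <- planted_term_id(group[grouped])
  pattern_class <- rep("other", n)
  pattern_class[grouped] <- class_of_group[group[grouped]]
  truth <- tibble::tibble(
    gene_id = gene_id,
    group = ifelse(grouped, as.character(group), "background"),
    planted_term = planted_term,
    pattern_class = pattern_class
  )
  list(expression = expression, truth = truth)
}

#' Simulate GO annotations with planted group enrichments
#'
#' Every gene receives `terms_per_gene` terms drawn uniformly without
#' replacement from a vocabulary of opaque GO identifiers. In addition,
#' each group's planted term (a reserved identifier outside the
#' vocabulary) is attached to group members with probability
#' `in_group_prob` and to all other genes with probability
#' `background_prob`, planting a recoverable overrepresentation signal.
#'
#' @param truth Truth tibble from [simulate_timecourse()].
#' @param terms_per_gene Background terms per gene (default 3).
#' @param in_group_prob Probability a group member carries its group's
#'   planted term (default 0.5).
#' @param background_prob Probability a non-member carries the planted
#'   term (default 0.05).
#' @param vocabulary_size Size of the background term vocabulary
#'   (default 200).
#' @param seed Integer seed.
#' @return An annotation tibble (`gene_id`, `term`), distinct pairs.
#' @export
simulate_annotations <- function(truth, terms_per_gene = 3,
                                 in_group_prob = 0.5,
                                 background_prob = 0.05,
                                 vocabulary_size = 200, seed = 1) {
  stopifnot(terms_per_gene >= 0, vocabulary_size >= terms_per_gene,
            in_group_prob >= 0, in_group_prob <= 1,
            background_prob >= 0, background_prob <= 1)
  set.seed(seed)
  n <- nrow(truth)
  vocab <- sprintf("GO:%07d", seq_len(vocabulary_size))
  base <- NULL
  if (terms_per_gene > 0) {
    idx <- vapply(seq_len(n),
                  function(i) sample.int(vocabulary_size, terms_per_gene),
                  integer(terms_per_gene))
    base <- tibble::tibble(
      gene_id = rep(truth$gene_id, each = terms_per_gene),
      term = vocab[as.vector(idx)]
    )
  }
  groups <- setdiff(unique(truth$group), "background")
  planted <- purrr::map_dfr(sort(as.integer(groups)), function(g) {
    member <- truth$group == as.character(g)
    p <- ifelse(member, in_group_prob, background_prob)
    hit <- stats::runif(n) < p
    tibble::tibble(gene_id = truth$gene_id[hit], term = planted_term_id(g))
  })
  dplyr::distinct(dplyr::bind_rows(base, planted)) |>
    dplyr::arrange(.data$gene_id, .data$term)
}
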