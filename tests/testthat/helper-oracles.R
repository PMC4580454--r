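# Independent oracles and small fixture builders used across tests.

# Brute-force mean absolute consecutive difference (explicit loop).
mn_oracle <- function(x) {
  s <- 0
  for (t in seq_len(length(x) - 1)) {
    s <- s + abs(x[t + 1] - x[t])
  }
  s / (length(x) - 1)
}

# Exhaustive one-sided hypergeometric tail from first principles:
# enumerate every table consistent with the margins and sum P(X >= a).
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + c        # genes with the term
  n2 <- b + d       # genes without the term
  k <- a + b        # group size
  xs <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k)
  sum(exp(logp[xs >= a]))
}

# Build an expression tibble from a numeric matrix.
make_expr <- function(mat, design, ids = sprintf("g%03d", seq_len(nrow(mat)))) {
  colnames(mat) <- design$label
  dplyr::bind_cols(tibble::tibble(gene_id = ids), tibble::as_tibble(mat))
}

# A clean "post-normalization" instance: template rows plus z-scale noise.
make_template_instance <- function(design, k = 7, per_group = 100,
                                   noise_sd = 0.2) {
  templates <- group_templates(design, k)
  truth <- rep(seq_len(k), each = per_group)
  m <- templates[truth, , drop = FALSE] +
    matrix(rnorm(length(truth) * nrow(design), sd = noise_sd),
           nrow = length(truth))
  list(rel = make_expr(m, design), truth = truth)
}
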