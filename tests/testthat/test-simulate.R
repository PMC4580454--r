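test_that("group templates are unit-variance, mean-zero, and bounded in number", {
  design <- diel_design()
  tpl <- group_templates(design, 9)
  expect_equal(dim(tpl), c(9, 7))
  expect_equal(rowMeans(tpl), rep(0, 9), tolerance = 1e-12)
  expect_equal(apply(tpl, 1, sd), rep(1, 9), tolerance = 1e-12)
  expect_error(group_templates(design, 10), "available templates")
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_timecourse(n_groups = 3, genes_per_group = 10,
                           n_background = 20, seed = 99)
  b <- simulate_timecourse(n_groups = 3, genes_per_group = 10,
                           n_background = 20, seed = 99)
  expect_identical(a, b)
  c <- simulate_timecourse(n_groups = 3, genes_per_group = 10,
                           n_background = 20, seed = 100)
  expect_false(identical(a$expression, c$expression))

  ann1 <- simulate_annotations(a$truth, seed = 7)
  ann2 <- simulate_annotations(a$truth, seed = 7)
  expect_identical(ann1, ann2)
})

test_that("all simulated FPKM values are strictly positive and finite", {
  sim <- simulate_timecourse(n_groups = 7, genes_per_group = 20,
                             n_background = 100, seed = 5)
  vals <- as.matrix(sim$expression[, -1])
  expect_true(all(is.finite(vals)))
  expect_true(all(vals > 0))
})

test_that("in the noiseless limit each gene's z-profile equals its group template", {
  design <- diel_design()
  sim <- simulate_timecourse(design, n_groups = 7, genes_per_group = 5,
                             n_background = 0, baseline_log_sd = 0,
                             noise_sd = 0, seed = 1)
  rel <- zscore_rows(sim$expression, design)
  templates <- group_templates(design, 7)
  m <- as.matrix(rel[, design$label])
  for (i in seq_len(nrow(m))) {
    g <- as.integer(sim$truth$group[sim$truth$gene_id == rel$gene_id[i]])
    # z-normalization of b*exp(a*z_g) is a monotone distortion of z_g;
    # peak position and ordering agree, and for spike templates the
    # renormalized shape is numerically close to the template
    expect_equal(which.max(m[i, ]), which.max(templates[g, ]))
  }
})

test_that("grouped genes stochastically dominate background in MeanNeighbor score", {
  design <- diel_design()
  ok <- vapply(1:20, function(s) {
    sim <- simulate_timecourse(design, seed = s)
    sc <- score_genes(sim$expression, design)
    truth <- sim$truth$group[match(sc$gene_id, sim$truth$gene_id)]
    grouped <- sc$score[truth != "background"]
    background <- sc$score[truth == "background"]
    median(grouped) > quantile(background, 0.9)
  }, logical(1))
  expect_true(all(ok))
})

test_that("planted-term probabilities hit their extreme cases", {
  sim <- simulate_timecourse(n_groups = 2, genes_per_group = 10,
                             n_background = 30, seed = 2)
  ann <- simulate_annotations(sim$truth, terms_per_gene = 0,
                              in_group_prob = 1, background_prob = 0,
                              seed = 3)
  universe <- sim$truth$gene_id
  g1 <- sim$truth$gene_id[sim$truth$group == "1"]
  counts <- contingency_counts(g1, unique(sim$truth$planted_term[sim$truth$group == "1"]),
                               ann, universe)
  expect_equal(counts$a, 10)
  expect_equal(counts$c, 0)
})

test_that("a planted term with equal probabilities carries no group signal", {
  sim <- simulate_timecourse(n_groups = 2, genes_per_group = 25,
                             n_background = 150, seed = 4)
  universe <- sim$truth$gene_id
  g1 <- sim$truth$gene_id[sim$truth$group == "1"]
  term1 <- unique(sim$truth$planted_term[sim$truth$group == "1"])
  ps <- vapply(1:50, function(s) {
    ann <- simulate_annotations(sim$truth, terms_per_gene = 0,
                                in_group_prob = 0.2, background_prob = 0.2,
                                seed = s)
    rec <- enrich_group(g1, ann, universe)
    p <- rec$p_value[rec$term == term1]
    if (length(p) == 0) 1 else p
  }, numeric(1))
  expect_gte(median(ps), 0.05)
})

test_that("designed pattern classes follow the template peak positions", {
  design <- diel_design()
  sim <- simulate_timecourse(design, n_groups = 7, genes_per_group = 1,
                             n_background = 1, seed = 6)
  class_by_group <- sim$truth$pattern_class[sim$truth$group != "background"]
  # groups are spike templates at D6, D10, L1, L4, L6, L10, D1 in order
  expect_equal(class_by_group,
               c("other", "dark_to_dawn_peak", "dark_to_dawn_peak",
                 "late_light_peak", "late_light_peak", "late_light_peak",
                 "other"))
  expect_equal(sim$truth$pattern_class[sim$truth$group == "background"],
               "other")
})
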