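test_that("contingency_counts performs the direct set arithmetic", {
  ann <- tibble::tibble(gene_id = c("g1", "g3"), term = "GO:A")
  universe <- c("g1", "g2", "g3", "g4")
  counts <- contingency_counts(c("g1", "g2"), "GO:A", ann, universe)
  expect_equal(unlist(counts), c(a = 1, b = 1, c = 1, d = 1))

  nobody <- contingency_counts(c("g1", "g2"), "GO:Z", ann, universe)
  expect_equal(unlist(nobody[c("a", "c")]), c(a = 0, c = 0))

  all_in <- contingency_counts(universe, "GO:A", ann, universe)
  expect_equal(unlist(all_in[c("c", "d")]), c(c = 0, d = 0))

  expect_error(contingency_counts(c("g1", "g9"), "GO:A", ann, universe),
               "outside universe: g9")
})

test_that("fisher_overrep_p matches closed-form and degenerate cases", {
  expect_equal(fisher_overrep_p(0, 10, 5, 100), 1)
  expect_equal(fisher_overrep_p(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
})

test_that("fisher_overrep_p equals exhaustive tail summation on random tables", {
  set.seed(41)
  for (i in 1:500) {
    k <- sample(1:50, 1)     # group size
    m <- sample(0:50, 1)     # term total
    n_univ <- k + m + sample(0:50, 1)
    a <- sample(max(0, k + m - n_univ):min(k, m), 1)
    b <- k - a
    c <- m - a
    d <- n_univ - k - c
    expect_equal(fisher_overrep_p(a, b, c, d), hyper_tail_oracle(a, b, c, d),
                 tolerance = 1e-12)
  }
})

test_that("overrepresentation p is monotone in a with margins fixed", {
  # margins: term total 10, group size 12, universe 40
  ps <- vapply(0:10, function(a) {
    fisher_overrep_p(a, 12 - a, 10 - a, 40 - 12 - (10 - a))
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("a planted 50%-vs-5% term is significant at 0.05", {
  set.seed(42)
  universe <- sprintf("g%04d", 1:1000)
  group <- universe[1:50]
  carriers <- c(sample(group, 25), sample(setdiff(universe, group), 47))
  ann <- tibble::tibble(gene_id = carriers, term = "GO:planted")
  rec <- enrich_group(group, ann, universe)
  expect_equal(rec$a[rec$term == "GO:planted"], 25)
  expect_lt(rec$p_value[rec$term == "GO:planted"], 0.05)
  expect_true(rec$significant[rec$term == "GO:planted"])
})

test_that("overflowing 0.05 triggers re-assessment at 1e-7 with the cutoff recorded", {
  # 120 terms, each carried by 5 members of a 50-gene group and nobody else:
  # every term lands near p ~ 9e-4 (significant at 0.05, not at 1e-7)
  universe <- sprintf("g%03d", 1:200)
  group <- universe[1:50]
  ann <- purrr::map_dfr(1:120, function(t) {
    tibble::tibble(gene_id = group[((t - 1) * 5 + 0:4) %% 50 + 1],
                   term = sprintf("GO:%04d", t))
  })
  rec <- enrich_group(group, ann, universe)
  expect_equal(nrow(rec), 120)
  expect_true(all(rec$p_value <= 0.05))        # would overflow at 0.05
  expect_equal(unique(rec$cutoff_applied), 1e-7)
  expect_equal(rec$significant, rec$p_value <= 1e-7)
})

test_that("a group with unannotated members only yields no records", {
  ann <- tibble::tibble(gene_id = "g9", term = "GO:A")
  rec <- enrich_group(c("g1", "g2"), ann, sprintf("g%d", 1:9))
  expect_equal(nrow(rec), 0)
  expect_error(enrich_group(character(), ann, "g1"), "non-empty")
})

test_that("records are sorted by p-value with term-id tie-break and percentages check out", {
  set.seed(43)
  universe <- sprintf("g%03d", 1:100)
  group <- universe[1:20]
  ann <- tibble::tibble(
    gene_id = sample(universe, 200, replace = TRUE),
    term = sample(sprintf("GO:%02d", 1:10), 200, replace = TRUE)
  ) |> dplyr::distinct()
  rec <- enrich_group(group, ann, universe)
  expect_equal(order(rec$p_value, rec$term), seq_len(nrow(rec)))
  expect_equal(rec$pct_in_group, 100 * rec$a / (rec$a + rec$b))
  expect_equal(rec$pct_in_genome,
               100 * (rec$a + rec$c) / (rec$a + rec$b + rec$c + rec$d))
})

test_that("overrepresentation_bars keeps significant records only", {
  rec <- tibble::tibble(
    term = c("GO:A", "GO:B"), a = c(19, 1), b = c(31, 49),
    c = c(5, 40), d = c(945, 910),
    p_value = c(1e-20, 0.9),
    pct_in_group = c(38, 2), pct_in_genome = c(2.4, 4.1),
    significant = c(TRUE, FALSE), cutoff_applied = 0.05
  )
  bars <- overrepresentation_bars(rec)
  expect_equal(bars$term, "GO:A")
  expect_equal(bars$pct_in_group, 38)
})

test_that("the BH option adjusts p-values and gates significance on them", {
  universe <- sprintf("g%03d", 1:100)
  group <- universe[1:20]
  ann <- tibble::tibble(gene_id = c(group[1:10], universe[21:25]),
                        term = rep(c("GO:A", "GO:B"), c(10, 5)))
  rec <- enrich_group(group, ann, universe, fdr = TRUE)
  expect_true("p_adjusted" %in% names(rec))
  expect_equal(rec$p_adjusted, p.adjust(rec$p_value, "BH"))
  expect_equal(rec$significant, rec$p_adjusted <= rec$cutoff_applied)
})
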