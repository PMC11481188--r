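test_that("Fisher enrichment builds the right table and two-tailed p", {
  universe <- sprintf("g%02d", 1:20)
  set_genes <- universe[1:10]
  pathway <- c(universe[1:8], universe[11:12])   # overlap 8 -> [[8,2],[2,8]]
  fe <- fisher_enrichment(set_genes, pathway, universe)
  expect_equal(unname(fe$table[1, 1]), 8)
  expect_equal(fe$p, 0.02301414, tolerance = 1e-6)
  expect_equal(fe$p, fisher_enumeration(8, 2, 2, 8), tolerance = 1e-10)

  # independent set and pathway with balanced margins: central table, p = 1
  fe_null <- fisher_enrichment(universe[1:10], c(universe[1:5], universe[11:15]),
                               universe)
  expect_equal(fe_null$p, 1)

  # pathway fully inside an equally sized set: most extreme table
  fe_ext <- fisher_enrichment(universe[1:5], universe[1:5], universe)
  expect_equal(fe_ext$p, fisher_enumeration(5, 0, 0, 15), tolerance = 1e-10)
  expect_error(fisher_enrichment("a", "a", character(0)),
               class = "agecourse_invalid_argument")
})

test_that("Fisher p equals the hypergeometric enumeration oracle on random tables", {
  set.seed(17)
  for (i in 1:80) {
    tot <- sample(4:40, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c_ <- cuts[3] - cuts[2]; d <- tot - cuts[3]
    got <- fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    expect_equal(got, fisher_enumeration(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("BH adjustment is the monotone step-up with cap at 1", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(1)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "agecourse_invalid_argument")
})

test_that("activation z-score follows sum(x)/sqrt(N)", {
  expect_equal(activation_zscore(rep(1, 8)), 8 / sqrt(8))
  expect_equal(activation_zscore(c(1, 1, -1, -1)), 0)
  expect_equal(activation_zscore(1), 1)
  expect_equal(activation_zscore(rep(1, 9), denominator = "n"), 1)
  set.seed(2)
  for (n in c(1, 3, 10, 25)) {
    s <- sample(c(-1, 1), 1)
    expect_equal(abs(activation_zscore(rep(s, n))), sqrt(n))
  }
  expect_error(activation_zscore(numeric(0)), class = "agecourse_invalid_argument")
  expect_error(activation_zscore(c(1, 0)), class = "agecourse_invalid_argument")
})

test_that("binomial skew test reproduces exact two-tailed enumeration", {
  expect_equal(binomial_skew_test(12, 24), 1)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(5:120, 1)
    k <- sample(0:n, 1)
    expect_equal(binomial_skew_test(k, n), binom_enumeration(k, n, 0.5),
                 tolerance = 1e-10)
  }
  expect_equal(binomial_skew_test(3, 10, 0.3), binom_enumeration(3, 10, 0.3),
               tolerance = 1e-10)
  expect_error(binomial_skew_test(5, 10, 0), class = "agecourse_invalid_argument")
  expect_error(binomial_skew_test(11, 10), class = "agecourse_invalid_argument")
})

test_that("directions come from module sign, overridden by post-vertex slope", {
  labels <- setNames(c(1L, 1L, 2L, 0L), c("g1", "g2", "g3", "g4"))
  stats <- data.frame(module = c("M1", "M2"), pearson_r = c(-0.5, 0.6),
                      p_value = c(0.01, 0.02))
  fits <- data.frame(transcript_id = c("g2", "g3"),
                     chosen_model = c("quadratic", "quadratic"),
                     b2_quad = c(0.4, -0.2))
  expect_warning(dd <- assign_directions(labels, stats, fits), "no direction")
  expect_equal(dd$direction[dd$transcript_id == "g1"], -1L)  # module r < 0
  expect_equal(dd$direction[dd$transcript_id == "g2"], 1L)   # B2 > 0 overrides
  expect_equal(dd$direction[dd$transcript_id == "g3"], -1L)  # B2 < 0
  expect_false("g4" %in% dd$transcript_id)                   # unassigned, no fit
  expect_equal(dd$fold_change, 2L * dd$direction)
  expect_equal(dd$p[dd$transcript_id == "g1"], 0.01)
})

test_that("pathway enrichment flags planted coherent sets and not null sets", {
  universe <- sprintf("g%03d", 1:300)
  set_genes <- universe[1:60]
  directions <- data.frame(transcript_id = set_genes,
                           direction = c(rep(1L, 40), rep(-1L, 20)))
  # the null set overlaps the query proportionally (no enrichment either way)
  pathways <- list(hit_up = universe[1:20],
                   hit_down = universe[41:60],
                   null = c(universe[55:60], universe[101:124]))
  res <- pathway_enrichment(directions, pathways, universe)
  expect_s3_class(res, "enrichment_result")
  expect_true(res$significant[res$pathway == "hit_up"])
  expect_true(res$significant[res$pathway == "hit_down"])
  expect_false(res$significant[res$pathway == "null"])
  expect_equal(res$z[res$pathway == "hit_up"], sqrt(20))
  expect_equal(res$z[res$pathway == "hit_down"], -sqrt(20))
  expect_true(all(res$bh_adjusted_p >= res$fisher_p))
  expect_true(all(abs(res$z) <= sqrt(res$n_overlap) + 1e-12, na.rm = TRUE))
})

test_that("BH thresholding controls the false discovery rate on a global null", {
  set.seed(19)
  n_path <- 500; reps <- 100
  fdr <- vapply(seq_len(reps), function(i) {
    p <- runif(n_path)
    r <- sum(bh_adjust(p) <= 0.05)
    if (r == 0) 0 else 1   # all discoveries are false under the global null
  }, 0)
  mc_sd <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(fdr) - 0.05), 4 * mc_sd + 1e-9)
})
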