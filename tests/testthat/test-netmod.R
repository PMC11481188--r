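test_that("soft adjacency is |r|^power with unit diagonal", {
  x <- 1:8
  y <- with_correlation(x, 0.5)
  m <- rbind(a = x, b = y, c = -x)
  adj <- soft_adjacency(m, power = 12)
  expect_equal(adj["a", "b"], 0.5^12, tolerance = 1e-10)
  expect_equal(adj["a", "c"], 1, tolerance = 1e-10)   # unsigned network
  expect_equal(diag(adj), c(a = 1, b = 1, c = 1))
  expect_equal(soft_adjacency(m, power = 1)["a", "b"], 0.5, tolerance = 1e-10)

  m2 <- rbind(a = x, const = rep(1, 8))
  expect_warning(adj2 <- soft_adjacency(m2), "constant")
  expect_equal(adj2["a", "const"], 0)
  expect_error(soft_adjacency(m[, 1:3]), class = "agecourse_invalid_argument")
})

test_that("topological overlap matches limits and the brute-force oracle", {
  expect_equal(topological_overlap(diag(4)), diag(4))

  full <- matrix(1, 3, 3)
  tom_full <- topological_overlap(full)
  expect_true(all(tom_full == 1))

  set.seed(5)
  for (n in c(3, 5, 6)) {
    a <- matrix(sample(seq(0, 1, 0.25), n * n, replace = TRUE), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    got <- topological_overlap(a)
    expect_equal(got, tom_bruteforce(a), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
    expect_equal(got, t(got))
  }
  expect_error(topological_overlap(matrix(c(0, 1, 0, 0), 2)),
               class = "agecourse_invalid_argument")
})

test_that("planted blocks are detected exactly and order-invariantly", {
  pb <- planted_blocks(n_per = 40, seed = 11)
  tom <- topological_overlap(soft_adjacency(pb$mat, power = 6))
  labels <- detect_modules(tom, min_module_size = 30)
  expect_equal(length(unique(labels[labels > 0])), 2)
  expect_equal(ari_oracle(labels, pb$truth), 1)

  perm <- sample(nrow(pb$mat))
  tom_p <- topological_overlap(soft_adjacency(pb$mat[perm, ], power = 6))
  labels_p <- detect_modules(tom_p, min_module_size = 30)
  expect_equal(ari_oracle(labels_p, labels[perm]), 1)
})

test_that("clusters below the minimum module size stay unassigned", {
  pb <- planted_blocks(n_per = 10, seed = 13)
  tom <- topological_overlap(soft_adjacency(pb$mat, power = 6))
  expect_warning(labels <- detect_modules(tom, min_module_size = 30),
                 "unassigned")
  expect_true(all(labels == 0))
})

test_that("eigengene equals the shared profile for identical members and flips consistently", {
  set.seed(21)
  profile <- rnorm(20)
  m <- matrix(rep(profile, each = 5), 5, byrow = FALSE)
  labels <- setNames(rep(1L, 5), rownames(m))
  eg <- module_eigengenes(m, labels)[, 1]
  expect_equal(cor(eg, profile), 1, tolerance = 1e-10)
  expect_equal(sd(eg), 1, tolerance = 1e-10)

  eg_flip <- module_eigengenes(-m, labels)[, 1]
  expect_equal(eg_flip, -eg, tolerance = 1e-8)
})

test_that("eigengene explains at least any single member's share of module variance", {
  set.seed(22)
  for (rep in 1:5) {
    m <- matrix(rnorm(8 * 12), 8, 12)
    scaled <- scale_per_transcript(m)
    eg <- module_eigengenes(m, rep(1L, 8))[, 1]
    share <- function(v) {
      proj <- scaled %*% v / sqrt(sum(v^2))
      sum(proj^2)
    }
    eg_share <- share(eg)
    for (i in 1:8) expect_gte(eg_share + 1e-9, share(scaled[i, ]))
  }
})

test_that("modules merge iff their eigengene dissimilarity is below threshold", {
  set.seed(31)
  n <- 30
  f <- rnorm(n)
  make_block <- function(center, k, sd) t(vapply(1:k, function(i)
    center + rnorm(n, 0, sd), numeric(n)))
  # blocks 1 and 2 share a profile (eigengene r ~ 0.95); block 3 is distant
  m <- rbind(make_block(f, 5, 0.2), make_block(f + rnorm(n, 0, 0.3), 5, 0.2),
             make_block(rnorm(n), 5, 0.2))
  labels <- rep(1:3, each = 5)
  merged <- merge_close_modules(m, labels, merge_threshold = 0.25)
  expect_equal(length(unique(merged[merged > 0])), 2)
  expect_equal(length(unique(merged[1:10])), 1)

  kept <- merge_close_modules(m, labels, merge_threshold = 0.01)
  expect_equal(length(unique(kept[kept > 0])), 3)
})

test_that("merge outcome ignores module label order on a clear hierarchy", {
  set.seed(33)
  n <- 24
  f <- rnorm(n)
  mk <- function(center) t(vapply(1:6, function(i) center + rnorm(n, 0, 0.15),
                                  numeric(n)))
  m <- rbind(mk(f), mk(f + rnorm(n, 0, 0.25)), mk(rnorm(n)))
  base_labels <- rep(1:3, each = 6)
  ref <- merge_close_modules(m, base_labels)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    merged <- merge_close_modules(m, perm[base_labels])
    expect_equal(ari_oracle(merged, ref), 1)
  }
})

test_that("age correlation applies the |r| and p thresholds jointly", {
  ages <- generate_ages(80, seed = 41)
  eg <- cbind(M1 = scale(ages)[, 1],
              M2 = with_correlation(ages, 0),
              M3 = with_correlation(ages, 0.29))
  eg <- apply(eg, 2, function(v) v / sd(v))
  st <- correlate_modules_with_age(eg, ages)
  expect_true(st$significant[1])
  expect_equal(st$pearson_r[1], 1, tolerance = 1e-9)
  expect_false(st$significant[2])
  # r = 0.29 is highly significant at n = 80 yet fails the effect-size rule
  expect_equal(st$pearson_r[3], 0.29, tolerance = 1e-9)
  expect_lt(st$p_value[3], 0.05)
  expect_false(st$significant[3])

  eg0 <- cbind(M1 = rep(0, 80))
  st0 <- correlate_modules_with_age(eg0, ages)
  expect_false(st0$significant[1])
  expect_true(is.na(st0$pearson_r[1]))
})

test_that("find_modules recovers the planted partition on a default cohort", {
  co <- simulate_cohort(seed = 8)
  norm <- preprocess_counts(co$expression$counts)
  ms <- find_modules(norm, co$ages)
  tt <- co$expression$truth_table
  truth <- tt$module_id[match(names(ms$labels), tt$transcript_id)]
  expect_gte(ari_oracle(truth, ms$labels), 0.8)
  expect_true(all(ms$age_stats$n_transcripts >= ms$params$min_module_size))
  # eigengenes have unit variance by construction
  expect_equal(unname(apply(ms$eigengenes, 2, sd)),
               rep(1, ncol(ms$eigengenes)), tolerance = 1e-8)
})
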