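test_that("alpha-diversity indices match hand-computed values", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(10)), 0)
  s_123 <- -(1 / 6 * log(1 / 6) + 2 / 6 * log(2 / 6) + 3 / 6 * log(3 / 6))
  expect_equal(shannon(c(1, 2, 3)), s_123, tolerance = 1e-12)
  expect_equal(shannon(c(1, 2, 3)), 1.011404, tolerance = 1e-6)

  expect_equal(evenness(c(7, 7, 7, 7, 7)), 1.0)
  expect_equal(evenness(c(1, 2, 3)), s_123 / log(3), tolerance = 1e-12)
  e1 <- evenness(c(10))
  expect_true(is.na(e1))
  expect_match(attr(e1, "reason"), "R = 1")

  ## S_obs = 5, F1 = 2, F2 = 1 -> 5 + 4/2 = 7
  expect_equal(chao1(c(1, 1, 2, 3, 4)), 7)
  expect_equal(chao1(c(3, 4, 5)), 3)  # no singletons: chao1 = S_obs
  ## bias-corrected branch: F1 = 3, F2 = 0, S_obs = 4 -> 4 + 3*2/2 = 7
  expect_equal(chao1(c(1, 1, 1, 5)), 7)

  expect_equal(goods_coverage(c(1, 1, 99, 99)), 99.0)
  expect_equal(goods_coverage(c(5, 10)), 100.0)
  expect_equal(goods_coverage(rep(1, 7)), 0.0)
})

test_that("diversity indices satisfy their structural bounds", {
  set.seed(11)
  for (rep in 1:50) {
    v <- stats::rpois(sample(3:40, 1), lambda = stats::runif(1, 0.5, 20))
    if (sum(v) == 0) v[1] <- 1
    r <- sum(v > 0)
    expect_gte(chao1(v), r)
    g <- goods_coverage(v)
    expect_gte(g, 0)
    expect_lte(g, 100)
    if (r >= 2) {
      ## Shannon is maximal at the uniform composition for fixed richness
      expect_lte(shannon(v), log(r) + 1e-12)
      ev <- evenness(v)
      expect_gte(ev, 0)
      expect_lte(ev, 1 + 1e-12)
    }
  }
})

test_that("rarefaction expectation is exact, monotone, and flags saturation", {
  one <- rarefaction_curve(c(0, 120), step = 50)
  expect_true(all(one$expected_taxa == 1))
  expect_equal(one$final_slope, 0)
  expect_true(one$saturated)

  set.seed(12)
  counts <- as.vector(stats::rmultinom(1, 2000, prob = stats::rgamma(40, 0.5)))
  counts <- counts[counts > 0]
  rc <- rarefaction_curve(counts, step = 300)
  expect_equal(rc$expected_taxa[length(rc$expected_taxa)], sum(counts > 0))
  expect_true(all(diff(rc$expected_taxa) >= -1e-9))

  ## Monte-Carlo oracle: mean taxa over random subsamples without
  ## replacement agrees with the hypergeometric expectation at every depth
  pool <- rep(seq_along(counts), counts)
  n_rep <- 3000
  for (d_idx in seq_along(rc$depths)) {
    d <- rc$depths[d_idx]
    draws <- replicate(n_rep, length(unique(sample(pool, d))))
    se <- stats::sd(draws) / sqrt(n_rep)
    expect_lt(abs(rc$expected_taxa[d_idx] - mean(draws)),
              3 * max(se, 1e-9) + 1e-9)
  }

  expect_error(rarefaction_curve(c(3, 4), step = 50), "below the grid step")
})

test_that("dendrogram pairing check scores identical pairs as fully paired", {
  set.seed(13)
  n_pat <- 8
  base <- matrix(stats::rpois(n_pat * 30, 20), n_pat, 30)
  counts <- base[rep(seq_len(n_pat), each = 2), ]
  ids <- as.vector(t(cbind(paste0("P", 1:n_pat, "_T"),
                           paste0("P", 1:n_pat, "_H"))))
  rownames(counts) <- ids
  colnames(counts) <- paste0("OTU", 1:30)
  tab <- otu_table(counts)
  pairing <- sample_pairing(paste0("P", 1:n_pat),
                            paste0("P", 1:n_pat, "_T"),
                            paste0("P", 1:n_pat, "_H"))
  expect_equal(as.numeric(pairing_cluster_check(tab, pairing)), 1.0)

  ## invariance to sample-row permutation
  perm <- sample(nrow(counts))
  tab_p <- otu_table(counts[perm, ], tab$taxonomy)
  expect_equal(as.numeric(pairing_cluster_check(tab_p, pairing)), 1.0)
})

test_that("i.i.d. samples rarely pair in the dendrogram", {
  n_pat <- 40
  frac <- vapply(1:50, function(s) {
    set.seed(300 + s)
    counts <- matrix(stats::rpois(2 * n_pat * 25, 15), 2 * n_pat, 25)
    rownames(counts) <- c(paste0("P", 1:n_pat, "_T"),
                          paste0("P", 1:n_pat, "_H"))
    colnames(counts) <- paste0("OTU", 1:25)
    pairing <- sample_pairing(paste0("P", 1:n_pat),
                              paste0("P", 1:n_pat, "_T"),
                              paste0("P", 1:n_pat, "_H"))
    as.numeric(pairing_cluster_check(otu_table(counts), pairing))
  }, numeric(1))
  expect_gte(mean(frac < 0.5), 0.95)
})

test_that("paired signed-rank test is exact, symmetric, and guards zeros", {
  expect_error(paired_signed_rank(1:10, 1:10), "all differences are zero")

  res <- paired_signed_rank(1:10 + 1, 1:10)
  expect_true(res$exact)
  ## exhaustive: all-positive differences, two-sided p = 2 / 2^10
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(res$statistic, 55 - 10 * 11 / 4)

  swap <- paired_signed_rank(1:10, 1:10 + 1)
  expect_equal(swap$p_value, res$p_value)
  expect_equal(swap$statistic, -res$statistic)

  ## ties or n > 25 fall back to the normal approximation
  set.seed(14)
  a <- round(stats::rnorm(30), 1)
  b <- round(a + stats::rnorm(30, 0.3), 1)
  keep <- a != b
  res2 <- paired_signed_rank(a[keep], b[keep])
  expect_false(res2$exact)
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
})

test_that("diversity_profile aggregates the per-sample indices", {
  tab <- toy_otu()
  prof <- diversity_profile(tab)
  expect_equal(prof$sample_id, c("S1", "S2"))
  expect_equal(prof$richness, c(3, 3))
  expect_equal(prof$n_reads, c(6, 15))
  expect_equal(prof$shannon[1], shannon(c(1, 2, 3)))
  expect_equal(prof$n_singletons, c(1, 0))
})
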