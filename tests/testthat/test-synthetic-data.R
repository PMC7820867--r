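test_that("cytokine panel generation is seeded and validates arguments", {
  nm <- c("IL-8", "IL-6")
  p1 <- generate_cytokine_panel(5, nm, seed = 100)
  p2 <- generate_cytokine_panel(5, nm, seed = 100)
  p3 <- generate_cytokine_panel(5, nm, seed = 101)
  expect_identical(p1$values, p2$values)
  expect_false(identical(p1$values, p3$values))
  expect_equal(nrow(p1$values), 10)
  expect_equal(rownames(p1$values)[1:2], c("P001_T", "P001_H"))

  expect_error(generate_cytokine_panel(1, nm, seed = 1), ">= 2")
  expect_error(generate_cytokine_panel(5, c("IL-8", "IL-8"), seed = 1),
               "duplicate")
  expect_error(generate_cytokine_panel(5, nm, tissue_shift = c(1, 2, 3),
                                       seed = 1),
               "per cytokine")
  expect_error(generate_cytokine_panel(5, c("IL-8", "NotReal"), seed = 1),
               "NotReal")
})

test_that("zero tissue shift gives symmetric tumor/healthy marginals", {
  p <- generate_cytokine_panel(500, c("IL-8", "IL-6"), tissue_shift = 0,
                               seed = 42)
  lv <- log(p$values)
  tumor <- lv[grepl("_T$", rownames(lv)), ]
  healthy <- lv[grepl("_H$", rownames(lv)), ]
  d <- colMeans(tumor) - colMeans(healthy)
  ## paired design: difference of log means has sd sdlog*sqrt(2/n)
  se <- 1 * sqrt(2 / 500)
  expect_true(all(abs(d) < 4 * se))
})

test_that("a log-scale tissue shift is detected by the paired test", {
  rejections <- vapply(1:20, function(s) {
    p <- generate_cytokine_panel(200, c("IL-8", "IL-6"),
                                 tissue_shift = c(1.0, 0), seed = 500 + s)
    tumor <- p$values[grepl("_T$", rownames(p$values)), ]
    healthy <- p$values[grepl("_H$", rownames(p$values)), ]
    c(shift = paired_signed_rank(tumor[, 1], healthy[, 1])$p_value < 0.01,
      null = paired_signed_rank(tumor[, 2], healthy[, 2])$p_value < 0.01)
  }, logical(2))
  expect_gte(mean(rejections["shift", ]), 0.95)
  expect_lte(mean(rejections["null", ]), 0.2)
})

test_that("DM counts conserve depths and converge to symmetric proportions", {
  truth_sym <- ground_truth(
    rbind(log(rep(0.25, 4)), 0),
    data.frame(covariate = integer(), category = integer()),
    overdispersion = 50)
  X2 <- cbind(1, c(0.3, -0.3))
  y <- generate_dm_counts(X2, truth_sym, depths = c(100, 200), seed = 1)
  expect_equal(unname(rowSums(y$counts)), c(100, 200))

  n <- 2000
  Xn <- cbind(1, stats::rnorm(n))
  yy <- generate_dm_counts(Xn, truth_sym, depths = rep(1e4, n), seed = 2)
  expect_equal(unname(colMeans(yy$counts / 1e4)), rep(0.25, 4),
               tolerance = 0.02)

  expect_error(generate_dm_counts(X2, truth_sym, depths = c(100, 0),
                                  seed = 1),
               "positive integers")
  expect_error(generate_dm_counts(cbind(1, 1, 1)[, 1:3, drop = FALSE],
                                  truth_sym, depths = 5, seed = 1),
               "coefficient matrix")
})

test_that("an active coefficient shifts the category toward high covariates", {
  b <- rbind(log(c(0.3, 0.3, 0.2, 0.2)), c(0, 1.5, 0, 0))
  truth <- ground_truth(b, data.frame(covariate = 1, category = 2),
                        overdispersion = 50)
  hits <- vapply(1:50, function(s) {
    set.seed(7000 + s)
    x <- stats::rnorm(40)
    y <- generate_dm_counts(cbind(1, x), truth, depths = rep(1e4, 40),
                            seed = 7000 + s)
    p2 <- y$counts[, 2] / rowSums(y$counts)
    hi <- x >= stats::quantile(x, 0.75)
    lo <- x <= stats::quantile(x, 0.25)
    mean(p2[hi]) > mean(p2[lo])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("category totals match the implied DM marginal under the null", {
  ## Wald test of mean proportions against the Dirichlet-multinomial
  ## mean/covariance implied by an intercept-only truth
  p0 <- c(0.35, 0.2, 0.1, 0.35)
  tau <- 50
  depth <- 1e4
  n <- 500
  truth <- ground_truth(rbind(log(p0), 0),
                        data.frame(covariate = integer(),
                                   category = integer()),
                        overdispersion = tau)
  sig <- (diag(p0) - outer(p0, p0)) * (depth + tau) / (depth * (1 + tau))
  pv <- vapply(1:100, function(s) {
    set.seed(8000 + s)
    X <- cbind(1, stats::rnorm(n))
    y <- generate_dm_counts(X, truth, depths = rep(depth, n), seed = 8000 + s)
    d <- (colMeans(y$counts / depth) - p0)[1:3]
    w <- n * as.numeric(t(d) %*% solve(sig[1:3, 1:3]) %*% d)
    stats::pchisq(w, df = 3, lower.tail = FALSE)
  }, numeric(1))
  expect_gte(mean(pv > 0.01), 0.95)
})

test_that("paired studies are internally consistent and reproducible", {
  cfg <- study_config(n_patients = 12, n_active = 2, seed = 5)
  st <- generate_paired_study(cfg)
  expect_equal(nrow(st$truth$active_set), 2)
  expect_equal(ncol(st$composition$counts), cfg$n_categories)
  expect_equal(nrow(st$composition$counts), 24)

  ## all tables share sample ids; every patient has a tumor + healthy sample
  ids <- rownames(st$composition$counts)
  expect_setequal(ids, rownames(st$cytokine_panel$values))
  expect_setequal(ids, rownames(st$otu_table$counts))
  expect_setequal(ids, c(st$pairing$tumor_sample_id,
                         st$pairing$healthy_sample_id))

  ## OTU expansion conserves the generated composition exactly
  gen <- aggregate_to_rank(st$otu_table, "genus")
  resp <- build_composition_response(gen, cfg$n_categories - 1)
  expect_equal(sort(resp$category_names),
               sort(colnames(st$composition$counts)))
  for (nm in colnames(st$composition$counts)) {
    expect_equal(resp$counts[ids, nm], st$composition$counts[, nm])
  }

  st2 <- generate_paired_study(cfg)
  expect_identical(st2$composition$counts, st$composition$counts)
  st3 <- generate_paired_study(study_config(n_patients = 12, n_active = 2,
                                            seed = 6))
  expect_false(identical(st3$composition$counts, st$composition$counts))

  expect_error(study_config(n_categories = 1), "J >= 2")
  expect_error(study_config(n_cytokines = 0), "K >= 1")
  expect_error(study_config(n_cytokines = 2, n_categories = 2,
                            n_active = 5), "active pairs")
})

test_that("ground truth enforces sparsity outside the active set", {
  b <- rbind(log(c(0.5, 0.5)), c(0.7, 0.1))
  expect_error(ground_truth(b, data.frame(covariate = 1, category = 1),
                            overdispersion = 10),
               "exactly zero")
  expect_error(ground_truth(b * 0, data.frame(covariate = integer(),
                                              category = integer()),
                            overdispersion = -1),
               "positive")
})

test_that("study export writes the five tables the pipeline reads back", {
  st <- generate_paired_study(study_config(n_patients = 6, seed = 77))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(st, dir)
  expect_true(all(file.exists(paths)))
  back <- read_otu_table(paths["counts"], paths["taxonomy"])
  expect_identical(back$counts, st$otu_table$counts)
  pan <- read_cytokine_panel(paths["cytokines"])
  expect_equal(pan$values, st$cytokine_panel$values, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$overdispersion, st$truth$overdispersion)
})
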