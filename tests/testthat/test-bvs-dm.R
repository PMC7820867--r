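test_that("threshold map zeroes sub-threshold coefficients and is odd", {
  expect_equal(threshold_map(0.3, 0.5), 0)
  expect_equal(threshold_map(-0.91, 0.5), -0.91)
  expect_equal(threshold_map(0.5, 0.5), 0.5)  # boundary included
  b <- seq(-2, 2, by = 0.25)
  expect_equal(threshold_map(-b, 0.7), -threshold_map(b, 0.7))
  expect_error(threshold_map(1, 0), "positive")
})

test_that("the DM regression likelihood is the sum of per-sample log pmfs", {
  ## single sample, theta = 0 gives alpha = (1, 1)
  theta0 <- matrix(0, 2, 2)
  X1 <- matrix(c(1, 0.4), 1, 2)
  expect_equal(dm_reg_loglik(theta0, X1, matrix(c(1, 0), 1, 2)), log(0.5))

  set.seed(21)
  n <- 12
  X <- cbind(1, stats::rnorm(n))
  theta <- rbind(log(c(4, 2, 3)), c(0.5, -0.2, 0))
  Y <- matrix(stats::rpois(n * 3, 30), n, 3)
  alpha <- exp(X %*% theta)
  by_hand <- sum(vapply(seq_len(n),
                        function(i) dm_logpmf(Y[i, ], alpha[i, ]),
                        numeric(1)))
  expect_equal(dm_reg_loglik(theta, X, Y), by_hand, tolerance = 1e-12)

  ## an all-zero covariate row contributes nothing
  X3 <- cbind(X, stats::rnorm(n))
  theta3 <- rbind(theta, 0)
  expect_equal(dm_reg_loglik(theta3, X3, Y), by_hand, tolerance = 1e-12)

  expect_error(dm_reg_loglik(theta, X, Y[, 1:2]), "dimension mismatch")
  expect_error(dm_reg_loglik(theta * 500, X, Y), "overflows at sample")
})

test_that("the sampler is reproducible and its summaries are well formed", {
  st <- generate_paired_study(study_config(n_patients = 12, seed = 51))
  slice <- tumor_slice(st)
  X <- standardize_covariates(slice$panel)
  cfg <- bvs_config(n_iterations = 2500, burn_in = 500, seed = 3)
  r1 <- suppressWarnings(run_bvs(X, slice$response, cfg))
  r2 <- suppressWarnings(run_bvs(X, slice$response, cfg))
  expect_identical(r1$chains$theta, r2$chains$theta)
  expect_identical(r1$ppi, r2$ppi)
  expect_identical(r1$posterior_mean, r2$posterior_mean)

  expect_true(all(r1$ppi >= 0 & r1$ppi <= 1))
  expect_equal(unname(r1$ppi[1, ]), rep(1, 4))
  expect_true(all(r1$posterior_mean[r1$ppi == 0] == 0))
  expect_equal(nrow(r1$chains$theta), 2000)

  r3 <- suppressWarnings(
    run_bvs(X, slice$response,
            bvs_config(n_iterations = 2500, burn_in = 500, seed = 4)))
  expect_false(identical(r1$chains$theta, r3$chains$theta))
})

test_that("sampler configuration is validated", {
  expect_error(bvs_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(bvs_config(prior_sd = 0), "positive")
  expect_error(bvs_config(threshold_prior = list(type = "spike")), "uniform")
  expect_error(bvs_config(threshold_prior = list(type = "fixed", t = -1)),
               "positive")
  expect_error(bvs_config(thin = 1.5), "positive integer")
  expect_error(bvs_config(indep_prob = 1), "indep_prob")

  st <- generate_paired_study(study_config(n_patients = 12, seed = 52))
  slice <- tumor_slice(st)
  X <- standardize_covariates(slice$panel)
  expect_error(run_bvs(X$X[1:5, ], slice$response$counts[1:5, ],
                       bvs_config()), "at least 10")
  no_int <- X$X
  no_int[, 1] <- 2
  expect_error(run_bvs(no_int, slice$response, bvs_config()), "intercept")
})

test_that("category relabeling permutes the posterior summaries", {
  ## the update order consumes randomness per (covariate, category) cell, so
  ## equality holds in distribution: compare PPIs within Monte-Carlo error
  st <- generate_paired_study(study_config(n_patients = 20, seed = 53))
  slice <- tumor_slice(st)
  X <- standardize_covariates(slice$panel)
  cfg <- bvs_config(n_iterations = 8000, burn_in = 2000, seed = 9)
  r <- suppressWarnings(run_bvs(X, slice$response, cfg))
  perm <- c(3, 1, 4, 2)
  y_perm <- composition_response(slice$response$counts[, perm])
  r_perm <- suppressWarnings(run_bvs(X, y_perm, cfg))
  expect_equal(colnames(r_perm$ppi), colnames(r$ppi)[perm])
  expect_lt(max(abs(r_perm$ppi - r$ppi[, perm])), 0.1)
})

test_that("default-study chains stay within the healthy acceptance band", {
  st <- generate_paired_study(study_config(seed = 54))
  slice <- tumor_slice(st)
  X <- standardize_covariates(slice$panel)
  r <- run_bvs(X, slice$response, bvs_config(seed = 2))
  acc <- r$acceptance_rates[["covariate"]]
  expect_gte(acc, 0.1)
  expect_lte(acc, 0.6)

  ## a signal-free study at high depth leaves inclusion moves essentially
  ## never accepted: the acceptance rate falls out of band and warns
  st0 <- generate_paired_study(study_config(seed = 21, n_active = 0))
  slice0 <- tumor_slice(st0)
  X0 <- standardize_covariates(slice0$panel)
  expect_warning(
    run_bvs(X0, slice0$response,
            bvs_config(n_iterations = 1500, burn_in = 500, seed = 2)),
    "acceptance rate")
})

test_that("association tables mirror the result with report-threshold masking", {
  st <- generate_paired_study(study_config(n_patients = 15, seed = 55))
  slice <- tumor_slice(st)
  X <- standardize_covariates(slice$panel)
  r <- suppressWarnings(
    run_bvs(X, slice$response,
            bvs_config(n_iterations = 3000, burn_in = 1000, seed = 5)))
  tabs <- render_association_tables(r)
  expect_equal(unname(unlist(tabs$ppi[1, ])), rep(1, 4))
  expect_identical(rownames(tabs$ppi), rownames(tabs$posterior_mean))
  expect_identical(colnames(tabs$ppi), colnames(tabs$posterior_mean))
  ## sub-threshold (and in particular never-included) pairs print as 0.00
  masked <- as.matrix(tabs$posterior_mean[-1, ])[as.matrix(tabs$ppi[-1, ]) < 0.5]
  expect_true(all(masked == 0))
  full <- render_association_tables(r, keep_subthreshold = TRUE)
  expect_equal(as.matrix(full$posterior_mean),
               round(r$posterior_mean, 2), ignore_attr = TRUE)
})
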