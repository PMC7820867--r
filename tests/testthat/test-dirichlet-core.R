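test_that("dm_logpmf matches closed forms and a direct gamma-product oracle", {
  expect_equal(dm_logpmf(c(1, 0), c(1, 1)), log(0.5))
  expect_equal(exp(dm_logpmf(c(1, 2), c(2, 3))), 72 / 210, tolerance = 1e-12)

  set.seed(41)
  for (rep in 1:100) {
    j_dim <- sample(2:4, 1)
    n_tot <- sample(0:6, 1)
    counts <- as.vector(stats::rmultinom(1, n_tot, rep(1, j_dim)))
    alpha <- stats::runif(j_dim, 0.2, 5)
    expect_equal(exp(dm_logpmf(counts, alpha)),
                 dm_pmf_gamma_oracle(counts, alpha), tolerance = 1e-10)
  }
})

test_that("dm pmf sums to one over all count vectors and is permutation invariant", {
  set.seed(42)
  for (rep in 1:20) {
    j_dim <- sample(2:3, 1)
    n_tot <- sample(2:4, 1)
    alpha <- stats::runif(j_dim, 0.3, 8)
    grid <- enumerate_counts(n_tot, j_dim)
    total <- sum(apply(grid, 1, function(y) exp(dm_logpmf(y, alpha))))
    expect_equal(total, 1, tolerance = 1e-10)
  }
  y <- c(3, 0, 5)
  a <- c(0.7, 2.2, 1.1)
  perm <- c(3, 1, 2)
  expect_equal(dm_logpmf(y[perm], a[perm]), dm_logpmf(y, a))
})

test_that("dm pmf approaches the multinomial pmf in the large-concentration limit", {
  p <- c(0.5, 0.3, 0.2)
  y <- c(4, 3, 1)
  lim <- dm_logpmf(y, 1e6 * p)
  ref <- stats::dmultinom(y, prob = p, log = TRUE)
  expect_equal(lim, ref, tolerance = 1e-3)
})

test_that("dirichlet_logpdf matches Beta closed forms and integrates to one", {
  expect_equal(dirichlet_logpdf(c(0.3, 0.7), c(1, 1)), 0)
  expect_equal(dirichlet_logpdf(c(0.5, 0.5), c(2, 2)), log(1.5))
  set.seed(43)
  for (rep in 1:5) {
    a <- stats::runif(2, 0.5, 4)
    dens <- function(p) {
      vapply(p, function(pi) exp(dirichlet_logpdf(c(pi, 1 - pi), a)),
             numeric(1))
    }
    val <- stats::integrate(dens, 1e-9, 1 - 1e-9, rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
  expect_error(dirichlet_logpdf(c(0, 1), c(1, 1)), "interior")
  expect_error(dirichlet_logpdf(c(0.4, 0.4), c(1, 1)), "sum to 1")
})

test_that("counts_to_proportions gives interior rows that sum to one", {
  expect_equal(counts_to_proportions(c(0, 10), 0.5)[1, ],
               c(0.5 / 11, 10.5 / 11))
  set.seed(44)
  m <- matrix(rpois(60, 4), 10, 6)
  m[1, ] <- c(5, 0, 0, 0, 0, 0)
  p <- counts_to_proportions(m)
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(p > 0))
  ## zero pseudocount on an all-positive row reduces to plain proportions
  v <- c(2, 3, 5)
  expect_equal(counts_to_proportions(v, 0)[1, ], v / 10)
  expect_error(counts_to_proportions(c(0, 0)), "positive total")
})

test_that("dirichlet regression recovers intercept-only concentrations", {
  set.seed(7)
  n <- 2000
  a0 <- c(10, 6, 3, 12)
  p <- rdirichlet_rows(n, a0)
  fit <- fit_dirichlet_regression(matrix(1, n, 1), p)
  expect_true(fit$converged)
  expect_equal(exp(fit$coefficients[1, ]), a0, tolerance = 0.05)
})

test_that("dirichlet regression respects likelihood additivity and nesting", {
  set.seed(8)
  n <- 120
  x <- scale(stats::rnorm(n))[, 1]
  X <- cbind(1, x)
  alpha <- exp(X %*% rbind(log(c(5, 3, 4)), c(0.6, 0, -0.4)))
  p <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(3, alpha[i, ])
    g / sum(g)
  }, numeric(3)))
  fit <- fit_dirichlet_regression(X, p)
  fit2 <- fit_dirichlet_regression(rbind(X, X), rbind(p, p))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-4)
  expect_equal(fit2$log_likelihood, 2 * fit$log_likelihood, tolerance = 1e-6)

  null_fit <- fit_dirichlet_regression(matrix(1, n, 1), p)
  expect_gte(fit$log_likelihood, null_fit$log_likelihood)
})

test_that("coefficient RMSE over replicates shrinks with sample size", {
  b_true <- rbind(log(10 * c(0.4, 0.3, 0.3)), c(0.8, -0.5, 0))
  rmse <- vapply(c(100, 400, 1600), function(n) {
    errs <- vapply(1:20, function(r) {
      set.seed(1000 * n + r)
      x <- scale(stats::rnorm(n))[, 1]
      X <- cbind(1, x)
      alpha <- exp(X %*% b_true)
      p <- t(vapply(seq_len(n), function(i) {
        g <- stats::rgamma(3, alpha[i, ])
        g / sum(g)
      }, numeric(3)))
      fit <- fit_dirichlet_regression(X, p)
      mean((fit$coefficients - b_true)^2)
    }, numeric(1))
    sqrt(mean(errs))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("likelihood-ratio test handles boundary and textbook cases", {
  f <- list(log_likelihood = -10)
  expect_equal(lrt_pvalue(f, f, df = 4),
               list(statistic = 0, p_value = 1))
  stat_05 <- stats::qchisq(0.95, df = 1)
  out <- lrt_pvalue(list(log_likelihood = stat_05 / 2),
                    list(log_likelihood = 0), df = 1)
  expect_equal(out$p_value, 0.05, tolerance = 1e-10)
  expect_error(lrt_pvalue(list(log_likelihood = -20),
                          list(log_likelihood = -10), df = 2),
               "optimizer failure")
  expect_error(lrt_pvalue(f, f, df = 0), "positive integer")
})

test_that("degenerate designs are rejected with clear errors", {
  set.seed(9)
  p <- rdirichlet_rows(30, c(2, 2))
  X_bad <- cbind(1, rep(2, 30))  # constant covariate: rank deficient
  expect_error(fit_dirichlet_regression(X_bad, p), "rank deficient")
  expect_error(fit_dirichlet_regression(matrix(1, 1, 1), p[1, , drop = FALSE]),
               "fewer samples")
  expect_error(fit_dirichlet_regression(matrix(1, 30, 1), p * 2),
               "interior")
})
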