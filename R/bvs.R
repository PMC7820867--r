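#' Hard-thresholding map
#'
#' Sends a raw coefficient to 0 when its magnitude falls below the
#' threshold, and leaves it unchanged otherwise: the sparsity mechanism of
#' the variable-selection prior. Odd in its first argument.
#'
#' @param b Raw coefficient(s).
#' @param t Positive threshold.
#' @return `b * (abs(b) >= t)`.
#' @export
threshold_map <- function(b, t) {
  if (any(t <= 0)) stop("`t` must be positive")
  b * (abs(b) >= t)
}

#' Dirichlet-multinomial regression log-likelihood
#'
#' \eqn{\sum_i \log DM(y_i; \exp(x_i' \theta))} — the likelihood the
#' variable-selection sampler explores.
#'
#' @param theta Effective coefficient matrix, (K+1) x J.
#' @param X Design matrix (samples x (K+1)) or [standardize_covariates()]
#'   result.
#' @param Y A [composition_response()] or count matrix (samples x J).
#' @return Log-likelihood (scalar).
#' @export
dm_reg_loglik <- function(theta, X, Y) {
  if (inherits(X, "design_matrix")) X <- X$X
  if (inherits(Y, "composition_response")) Y <- Y$counts
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != nrow(theta) || ncol(Y) != ncol(theta)) {
    stop("dimension mismatch between theta, X and Y")
  }
  eta <- X %*% theta
  bad <- which(!is.finite(exp(eta)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("linear predictor overflows at sample ", bad[1, 1],
         ", category ", bad[1, 2])
  }
  alpha <- exp(eta)
  sum(vapply(seq_len(nrow(Y)),
             function(i) dm_logpmf(Y[i, ], alpha[i, ]), numeric(1)))
}

#' Configuration of the variable-selection sampler
#'
#' @param n_iterations Total MCMC iterations (default 20000).
#' @param burn_in Discarded initial iterations (default 10000).
#' @param seed Integer seed.
#' @param prior_sd Sd of the independent Gaussian priors on the raw
#'   coefficients (default 1.0).
#' @param threshold_prior Either `list(type = "uniform", t_max = 1)` — the
#'   default Uniform(0, t_max) prior on the threshold — or
#'   `list(type = "fixed", t = <value>)`.
#' @param proposal_sd Random-walk sd for coefficient updates (default 0.2).
#' @param t_proposal_sd Random-walk sd for the threshold update (defaults
#'   to `proposal_sd`).
#' @param indep_prob Probability that a covariate update proposes a fresh
#'   draw from the prior instead of a local random walk (default 0.2).
#'   These independence moves jump the inclusion/exclusion boundary, which
#'   a small-step random walk crosses only slowly.
#' @param thin Keep every `thin`-th post-burn-in draw (default 1).
#' @return List of class `bvs_config`.
#' @export
bvs_config <- function(n_iterations = 20000, burn_in = 10000, seed = 1,
                       prior_sd = 1.0,
                       threshold_prior = list(type = "uniform", t_max = 1.0),
                       proposal_sd = 0.2, t_proposal_sd = proposal_sd,
                       indep_prob = 0.2, thin = 1) {
  if (burn_in >= n_iterations) stop("`burn_in` must be below `n_iterations`")
  if (prior_sd <= 0 || proposal_sd <= 0 || t_proposal_sd <= 0) {
    stop("sds must be positive")
  }
  if (!threshold_prior$type %in% c("uniform", "fixed")) {
    stop("threshold_prior$type must be 'uniform' or 'fixed'")
  }
  if (threshold_prior$type == "uniform" && threshold_prior$t_max <= 0) {
    stop("t_max must be positive")
  }
  if (threshold_prior$type == "fixed" && threshold_prior$t <= 0) {
    stop("fixed threshold must be positive")
  }
  if (thin < 1 || thin != round(thin)) stop("`thin` must be a positive integer")
  if (indep_prob < 0 || indep_prob >= 1) stop("`indep_prob` must be in [0, 1)")
  structure(list(n_iterations = n_iterations, burn_in = burn_in, seed = seed,
                 prior_sd = prior_sd, threshold_prior = threshold_prior,
                 proposal_sd = proposal_sd, t_proposal_sd = t_proposal_sd,
                 indep_prob = indep_prob, thin = thin),
            class = "bvs_config")
}

#' Bayesian variable selection in Dirichlet-multinomial regression
#'
#' Step two of the association analysis. Raw coefficients carry independent
#' Gaussian priors and are mapped to effective coefficients by hard
#' thresholding at a (by default random, Uniform-prior) threshold;
#' intercepts are never thresholded, so their posterior inclusion
#' probability is 1 by construction. A Metropolis-within-Gibbs sampler
#' explores the model space: element-wise updates of the raw coefficients (a
#' mixture of Gaussian random walks and occasional independence draws from
#' the prior, which jump the inclusion boundary) plus a random walk on the
#' threshold; the posterior
#' probability of inclusion (PPI) of a cytokine-category pair is the
#' fraction of retained draws in which its effective coefficient is
#' nonzero, and the reported posterior mean is conditional on inclusion
#' (exactly 0 for pairs never included).
#'
#' The reported covariate acceptance rate counts only likelihood-relevant
#' proposals (those that change an effective coefficient); prior-only moves
#' of excluded entries are near-automatic accepts and would mask poor
#' tuning. A rate outside `[0.1, 0.6]` triggers a tuning warning (the
#' all-proposals rate is reported alongside as `covariate_all`); K above 12
#' at default iteration counts triggers a runtime warning.
#'
#' @param X Design matrix (samples x (K+1), intercept first) or
#'   [standardize_covariates()] result.
#' @param Y A [composition_response()] (or samples x J count matrix).
#' @param config A [bvs_config()].
#' @return Object of class `bvs_result`: `ppi` and `posterior_mean`
#'   ((K+1) x J matrices), `chains` (retained effective-coefficient and
#'   threshold draws), `acceptance_rates`, `seed`, `config`.
#' @export
run_bvs <- function(X, Y, config = bvs_config()) {
  stopifnot(inherits(config, "bvs_config"))
  dm <- if (inherits(X, "design_matrix")) X else NULL
  if (!is.null(dm)) X <- dm$X
  if (inherits(Y, "composition_response")) Y <- Y$counts
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  p_dim <- ncol(X)
  j_dim <- ncol(Y)
  if (nrow(Y) != n) stop("row mismatch between X and Y")
  if (n < 10) stop("need at least 10 samples")
  if (p_dim < 2) stop("need at least one covariate besides the intercept")
  if (p_dim - 1 > 12) {
    warning("K = ", p_dim - 1, " covariates: expect long runtimes at the ",
            "default iteration count")
  }
  if (any(X[, 1] != 1)) stop("first design column must be the intercept")

  tp <- config$threshold_prior
  t_fixed <- tp$type == "fixed"
  t_max <- if (t_fixed) Inf else tp$t_max
  t_init <- if (t_fixed) tp$t else tp$t_max / 2

  ## deterministic start: intercepts at log mean proportions scaled to total
  ## concentration 10; raw covariate coefficients 0 (excluded at iteration 0)
  props <- colSums(Y) / sum(Y)
  b_init <- matrix(0, p_dim, j_dim)
  b_init[1, ] <- log(props * 10)
  theta0 <- b_init  # zeros thresholded anyway
  ll0 <- dm_reg_loglik(theta0, X, Y)
  if (!is.finite(ll0)) stop("non-finite likelihood at initialization")

  set.seed(config$seed)
  raw <- .bvs_mcmc_cpp(X, Y, b_init, t_init,
                       as.integer(config$n_iterations),
                       as.integer(config$burn_in),
                       as.integer(config$thin),
                       config$prior_sd, config$proposal_sd,
                       config$t_proposal_sd, t_max, t_fixed,
                       config$indep_prob)

  draws <- raw$theta_draws  # n_kept x (P*J), column-major over (k, j)
  included <- draws != 0
  ppi <- matrix(colMeans(included), p_dim, j_dim)
  ppi[1, ] <- 1  # intercepts are never thresholded
  post_mean <- matrix(0, p_dim, j_dim)
  for (idx in seq_len(p_dim * j_dim)) {
    inc <- included[, idx]
    if (any(inc)) {
      post_mean[idx] <- mean(draws[inc, idx])
    }
  }
  cov_names <- if (!is.null(dm)) c("intercept", dm$covariate_names) else
    if (!is.null(colnames(X))) c("intercept", colnames(X)[-1]) else
      c("intercept", paste0("covariate_", seq_len(p_dim - 1)))
  cat_names <- if (!is.null(colnames(Y))) colnames(Y) else
    paste0("category_", seq_len(j_dim))
  dimnames(ppi) <- dimnames(post_mean) <- list(cov_names, cat_names)

  acc <- raw$acceptance
  if (is.finite(acc[["covariate"]]) &&
      (acc[["covariate"]] < 0.1 || acc[["covariate"]] > 0.6)) {
    warning("covariate-update acceptance rate ",
            round(acc[["covariate"]], 3),
            " outside [0.1, 0.6]; consider retuning proposal_sd")
  }

  structure(list(ppi = ppi, posterior_mean = post_mean,
                 chains = list(theta = draws, threshold = raw$t_draws),
                 acceptance_rates = acc,
                 seed = config$seed, config = config),
            class = "bvs_result")
}

#' @export
print.bvs_result <- function(x, ...) {
  cat("bvs_result:", nrow(x$ppi) - 1, "covariates x", ncol(x$ppi),
      "categories;", nrow(x$chains$theta), "retained draws\n")
  cat("acceptance rates:",
      paste(names(x$acceptance_rates),
            round(x$acceptance_rates, 3), sep = "=", collapse = ", "), "\n")
  cat("PPI:\n")
  print(round(x$ppi, 2))
  invisible(x)
}

#' Render the PPI and coefficient tables of a variable-selection run
#'
#' Produces the two presentation tables of the analysis: posterior
#' probabilities of inclusion, and posterior means with entries below the
#' PPI report threshold shown as 0.00 (set `keep_subthreshold = TRUE` to
#' show the conditional means of weakly supported pairs instead). Both are
#' rounded to 2 decimals and share row/column order.
#'
#' @param result A [run_bvs()] result.
#' @param ppi_report_threshold Report threshold on PPI (default 0.5).
#' @param keep_subthreshold Keep sub-threshold conditional means visible.
#' @return List with data frames `ppi` and `posterior_mean`.
#' @export
render_association_tables <- function(result, ppi_report_threshold = 0.5,
                                      keep_subthreshold = FALSE) {
  stopifnot(inherits(result, "bvs_result"))
  ppi <- round(result$ppi, 2)
  coef_tab <- result$posterior_mean
  if (!keep_subthreshold) {
    mask <- result$ppi < ppi_report_threshold
    mask[1, ] <- FALSE  # intercepts always reported
    coef_tab[mask] <- 0
  }
  coef_tab <- round(coef_tab, 2)
  list(ppi = as.data.frame(ppi),
       posterior_mean = as.data.frame(coef_tab))
}
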