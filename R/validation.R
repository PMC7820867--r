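## Exact-posterior validation utilities for the variable-selection sampler.
## These deliberately use a different algorithm (deterministic quadrature
## over the model space) than the MCMC they are used to check.

## Gauss-Legendre nodes/weights on [a, b] by Golub-Welsch (eigenvalues of
## the Jacobi matrix); deterministic, no external dependency.
.gauss_legendre <- function(n, a, b) {
  if (n == 1) return(list(x = (a + b) / 2, w = b - a))
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  jm <- matrix(0, n, n)
  jm[cbind(i, i + 1)] <- beta
  jm[cbind(i + 1, i)] <- beta
  e <- eigen(jm, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (b - a) / 2 * e$values[ord] + (a + b) / 2,
       w = (b - a) / 2 * 2 * e$vectors[1, ord]^2)
}

#' Exact posterior inclusion probabilities for the two-category,
#' one-covariate selection model
#'
#' Brute-force counterpart of [run_bvs()] for the smallest nontrivial case
#' (K = 1 covariate, J = 2 categories, fixed threshold): the posterior is
#' integrated by Gauss-Legendre quadrature over the four inclusion models
#' (each covariate-category coefficient in or out). Excluded coefficients
#' contribute their prior exclusion mass \eqn{P(|b| < t)} analytically;
#' included ones are integrated over the truncated region \eqn{|b| \ge t};
#' both intercepts are integrated on a grid centred at the log of the mean
#' proportions (scaled to total concentration 10). Deterministic, so it
#' serves as an independent oracle for the sampler's PPIs.
#'
#' @param X n x 2 design matrix (intercept column, one covariate).
#' @param Y n x 2 count matrix.
#' @param t Fixed positive threshold.
#' @param prior_sd Gaussian prior sd on raw coefficients.
#' @param n_int,n_cov Quadrature nodes for intercepts / per half of the
#'   covariate inclusion region.
#' @param int_halfwidth Intercept integration half-width around the centre.
#' @param cov_lim Covariate integration limit (prior sd units).
#' @return Named vector: PPI of the covariate effect on category 1 and 2.
#' @export
bvs_exact_ppi_k1j2 <- function(X, Y, t, prior_sd = 1, n_int = 40, n_cov = 20,
                               int_halfwidth = 3.5, cov_lim = 4.5) {
  X <- as.matrix(X)
  Y <- if (inherits(Y, "composition_response")) Y$counts else as.matrix(Y)
  stopifnot(ncol(X) == 2, ncol(Y) == 2, t > 0)
  x <- X[, 2]
  y1 <- Y[, 1]
  y2 <- Y[, 2]
  n_tot <- y1 + y2
  ctr <- log(10 * colSums(Y) / sum(Y))
  loglik <- function(b01, b02, th11, th12) {
    ll <- 0
    for (i in seq_along(x)) {
      a1 <- exp(b01 + x[i] * th11)
      a2 <- exp(b02 + x[i] * th12)
      a_tot <- a1 + a2
      ll <- ll + lgamma(a_tot) - lgamma(n_tot[i] + a_tot) +
        lgamma(y1[i] + a1) - lgamma(a1) +
        lgamma(y2[i] + a2) - lgamma(a2)
    }
    ll
  }
  g1 <- .gauss_legendre(n_int, ctr[1] - int_halfwidth, ctr[1] + int_halfwidth)
  g2 <- .gauss_legendre(n_int, ctr[2] - int_halfwidth, ctr[2] + int_halfwidth)
  pos <- .gauss_legendre(n_cov, t, cov_lim * prior_sd)
  cov_nodes <- c(-rev(pos$x), pos$x)
  cov_w <- c(rev(pos$w), pos$w)
  phi <- function(z) stats::dnorm(z, 0, prior_sd)
  excl_mass <- 2 * stats::pnorm(t, 0, prior_sd) - 1

  ## log of the evidence integral over intercepts x given coefficient node
  ## sets, chunked over the first intercept to bound memory
  log_evidence <- function(t1n, t1w, t2n, t2w) {
    parts <- vapply(seq_along(g1$x), function(i1) {
      g <- expand.grid(b02 = g2$x, t11 = t1n, t12 = t2n)
      w <- expand.grid(w2 = g2$w * phi(g2$x), w3 = t1w, w4 = t2w)
      lw <- loglik(g1$x[i1], g$b02, g$t11, g$t12) +
        log(g1$w[i1] * phi(g1$x[i1])) + log(w$w2) + log(w$w3) + log(w$w4)
      m <- max(lw)
      m + log(sum(exp(lw - m)))
    }, numeric(1))
    m <- max(parts)
    m + log(sum(exp(parts - m)))
  }
  inc_w <- cov_w * phi(cov_nodes)
  l_e00 <- 2 * log(excl_mass) + log_evidence(0, 1, 0, 1)
  l_e10 <- log(excl_mass) + log_evidence(cov_nodes, inc_w, 0, 1)
  l_e01 <- log(excl_mass) + log_evidence(0, 1, cov_nodes, inc_w)
  l_e11 <- log_evidence(cov_nodes, inc_w, cov_nodes, inc_w)
  lm <- max(l_e00, l_e01, l_e10, l_e11)
  ev <- exp(c(l_e00, l_e01, l_e10, l_e11) - lm)
  c(category_1 = (ev[3] + ev[4]) / sum(ev),
    category_2 = (ev[2] + ev[4]) / sum(ev))
}
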