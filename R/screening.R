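#' Marginal screening of cytokines by single-covariate Dirichlet regression
#'
#' Step one of the two-step association analysis (a sure-independence
#' screen): each cytokine in turn is the sole predictor of the composition
#' in a log-link Dirichlet regression, tested against the shared
#' intercept-only model by a likelihood-ratio test with J degrees of
#' freedom (one added coefficient per category). Cytokines are ranked by
#' ascending p-value with a deterministic tie-break (statistic descending,
#' then name); the raw p-values serve only to rank — no multiplicity
#' correction is applied or implied.
#'
#' A cytokine whose single-covariate fit fails (zero variance, optimizer
#' non-convergence) receives statistic 0 and p = 1 with a warning, so one
#' degenerate column never aborts the screen.
#'
#' @param panel A [cytokine_panel()] (censoring already applied if wanted).
#' @param response A [composition_response()] on the same samples, in the
#'   same order.
#' @param transform Covariate transform, see [standardize_covariates()].
#' @param pseudocount Pseudocount for [counts_to_proportions()] (the
#'   Dirichlet density needs interior compositions).
#' @param top_m How many top-ranked cytokines to mark selected (default 3).
#' @return Object of class `screening_result`: data frame `table` with
#'   columns cytokine, statistic, p_value, rank, selected; plus `selection`,
#'   `m`, `null_log_likelihood`.
#' @export
screen_cytokines <- function(panel, response, transform = "log1p_zscore",
                             pseudocount = 0.5, top_m = 3) {
  vals <- if (inherits(panel, "cytokine_panel")) panel$values else
    as.matrix(panel)
  counts <- response$counts
  if (nrow(vals) != nrow(counts)) {
    stop("sample mismatch between cytokine panel and composition response")
  }
  if (!is.null(rownames(vals)) && !is.null(rownames(counts)) &&
      !identical(rownames(vals), rownames(counts))) {
    stop("sample ids of panel and response disagree (order matters)")
  }
  k <- ncol(vals)
  if (k < 2) stop("need at least 2 cytokines to screen")
  j_dim <- ncol(counts)
  props <- counts_to_proportions(counts, pseudocount = pseudocount)
  x_int <- matrix(1, nrow(vals), 1, dimnames = list(rownames(vals),
                                                    "(Intercept)"))
  null_fit <- fit_dirichlet_regression(x_int, props)

  stats_v <- numeric(k)
  pvals <- numeric(k)
  for (c_idx in seq_len(k)) {
    res <- tryCatch({
      dm <- standardize_covariates(vals[, c_idx, drop = FALSE],
                                   transform = transform)
      fit <- fit_dirichlet_regression(dm, props)
      if (!fit$converged) {
        warning("fit for cytokine '", colnames(vals)[c_idx],
                "' did not converge; p set to 1")
        list(statistic = 0, p_value = 1)
      } else {
        lrt_pvalue(fit, null_fit, df = j_dim)
      }
    }, error = function(e) {
      warning("cytokine '", colnames(vals)[c_idx], "' could not be ",
              "screened (", conditionMessage(e), "); p set to 1")
      list(statistic = 0, p_value = 1)
    })
    stats_v[c_idx] <- res$statistic
    pvals[c_idx] <- res$p_value
  }
  ord <- order(pvals, -stats_v, colnames(vals))
  rank_v <- integer(k)
  rank_v[ord] <- seq_len(k)
  tab <- data.frame(cytokine = colnames(vals), statistic = stats_v,
                    p_value = pvals, rank = rank_v,
                    stringsAsFactors = FALSE)
  m_eff <- min(top_m, k)
  tab$selected <- tab$rank <= m_eff
  structure(list(table = tab,
                 selection = tab$cytokine[order(tab$rank)][seq_len(m_eff)],
                 m = m_eff,
                 null_log_likelihood = null_fit$log_likelihood),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("screening_result: ", nrow(x$table), " cytokines; top ", x$m,
      " selected: ", paste(x$selection, collapse = ", "), "\n", sep = "")
  print(x$table[order(x$table$rank), ], row.names = FALSE)
  invisible(x)
}

#' Names of the top-m screened cytokines
#'
#' @param result A [screen_cytokines()] result.
#' @param m How many (1 <= m <= number screened).
#' @return Character vector of length m in rank order; `select_top(r, m1)`
#'   is always a prefix of `select_top(r, m2)` for m1 < m2.
#' @export
select_top <- function(result, m) {
  stopifnot(inherits(result, "screening_result"))
  k <- nrow(result$table)
  if (m < 1 || m > k || m != round(m)) {
    stop("`m` must be an integer in 1..", k)
  }
  result$table$cytokine[order(result$table$rank)][seq_len(m)]
}
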