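#' Shannon diversity index (nats)
#'
#' \eqn{S = -\sum_i p_i \ln p_i} over the nonzero proportions of a count
#' vector, using the natural logarithm.
#'
#' @param counts Nonnegative count vector with at least one positive entry.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative count")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' \eqn{E = S / \ln R} with S the Shannon index and R the observed richness
#' (number of nonzero counts). Undefined for R <= 1 (the denominator is 0);
#' in that case `NA` is returned with an attribute giving the reason rather
#' than an error, since single-taxon samples are legitimate inputs.
#'
#' @param counts Nonnegative count vector.
#' @param base Logarithm base for both S and the denominator; default
#'   natural log (`exp(1)`), the package-wide Shannon convention.
#' @return Evenness in `[0, 1]`, or `NA` when richness < 2.
#' @export
evenness <- function(counts, base = exp(1)) {
  r <- sum(counts > 0)
  if (r <= 1) {
    return(structure(NA_real_, reason = paste0("richness R = ", r,
                                               "; evenness undefined")))
  }
  (shannon(counts) / log(base)) / (log(r) / log(base))
}

#' Chao1 richness estimator
#'
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} with \eqn{F_1, F_2} the numbers of taxa
#' observed exactly once and twice; when no doubletons are present the
#' bias-corrected form \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} avoids
#' the division by zero.
#'
#' @param counts Nonnegative count vector with at least one positive entry.
#' @return Chao1 estimate (always >= observed richness).
#' @export
chao1 <- function(counts) {
  if (sum(counts) <= 0) stop("all-zero count vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Good's coverage estimator (percent)
#'
#' \eqn{(1 - n/N) \times 100} where n is the number of singleton reads
#' (taxa seen exactly once) and N the total reads in the sample: the
#' estimated percentage of the community captured by sequencing.
#'
#' @param counts Nonnegative count vector with at least one read.
#' @return Coverage in percent, in `[0, 100]`.
#' @export
goods_coverage <- function(counts) {
  n_reads <- sum(counts)
  if (n_reads < 1) stop("empty sample")
  n_single <- sum(counts == 1)
  (1 - n_single / n_reads) * 100
}

#' Exact rarefaction curve with saturation flag
#'
#' Expected number of distinct taxa in a uniform random subsample of d reads
#' drawn without replacement, by the exact hypergeometric expectation
#' \deqn{E[S_d] = \sum_i \left[1 - \binom{N - N_i}{d} / \binom{N}{d}\right]}
#' evaluated on a step-spaced depth grid (plus the full depth N, so the
#' curve ends at the observed richness). Determinism comes free: no
#' subsampling is involved. The final slope is the difference quotient over
#' the last grid interval — the increment in taxon count per additional
#' read — and the sample is flagged saturated when it falls below
#' `slope_threshold`.
#'
#' @param counts Nonnegative count vector, total reads >= `step`.
#' @param step Depth-grid spacing in reads (default 50).
#' @param slope_threshold Saturation threshold on taxa gained per read
#'   (default 1e-5).
#' @return Object of class `rarefaction_curve`: list with `depths`,
#'   `expected_taxa`, `final_slope`, `saturated`.
#' @export
rarefaction_curve <- function(counts, step = 50, slope_threshold = 1e-5) {
  counts <- counts[counts > 0]
  n_reads <- sum(counts)
  if (step < 1 || step != round(step)) stop("`step` must be a positive integer")
  if (n_reads < step) {
    stop("total reads (", n_reads, ") below the grid step (", step, ")")
  }
  depths <- unique(c(seq(step, n_reads, by = step), n_reads))
  expected <- vapply(depths, function(d) {
    ## log-scale hypergeometric "absence" probability per taxon
    lp_absent <- lchoose(n_reads - counts, d) - lchoose(n_reads, d)
    sum(1 - exp(lp_absent))
  }, numeric(1))
  m <- length(depths)
  final_slope <- if (m >= 2) {
    (expected[m] - expected[m - 1]) / (depths[m] - depths[m - 1])
  } else 0
  structure(list(depths = depths, expected_taxa = expected,
                 final_slope = final_slope,
                 saturated = final_slope < slope_threshold),
            class = "rarefaction_curve")
}

#' Per-sample diversity profile
#'
#' Applies [shannon()], [evenness()], [chao1()], [goods_coverage()] and the
#' raw read/singleton counts to every row of an OTU table.
#'
#' @param table An [otu_table()].
#' @return Data frame with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `evenness`, `chao1`, `goods_coverage`, `n_reads`,
#'   `n_singletons`.
#' @export
diversity_profile <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  rows <- lapply(rownames(table$counts), function(s) {
    v <- table$counts[s, ]
    data.frame(sample_id = s,
               richness = sum(v > 0),
               shannon = shannon(v),
               evenness = as.numeric(evenness(v)),
               chao1 = chao1(v),
               goods_coverage = goods_coverage(v),
               n_reads = sum(v),
               n_singletons = sum(v == 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dendrogram pairing check for a paired-sample design
#'
#' Each sample row is normalized by its total count and square-root
#' transformed, then samples are clustered by complete-linkage on Euclidean
#' distance. A patient counts as "paired" when its tumor and healthy samples
#' merge with each other before either merges with any other sample — i.e.
#' the pair forms a singleton-singleton merge in the dendrogram. The
#' returned fraction is the dendrogram analogue of "x/40 sample pairs also
#' pair by microbial composition".
#'
#' @param table An [otu_table()] containing every paired sample.
#' @param pairing A [sample_pairing()].
#' @return Fraction of patients whose two samples are mutual first merges,
#'   with attribute `paired_patients` naming them.
#' @export
pairing_cluster_check <- function(table, pairing) {
  stopifnot(inherits(table, "otu_table"), inherits(pairing, "sample_pairing"))
  if (nrow(pairing) < 2) stop("need at least 2 patients")
  ids <- c(pairing$tumor_sample_id, pairing$healthy_sample_id)
  missing_ids <- setdiff(ids, rownames(table$counts))
  if (length(missing_ids) > 0) {
    stop("samples missing from count table: ",
         paste(missing_ids, collapse = ", "))
  }
  norm <- sqrt(table$counts / rowSums(table$counts))
  hc <- stats::hclust(stats::dist(norm, method = "euclidean"),
                      method = "complete")
  ## singleton-singleton merges: rows of $merge with two negative entries
  leaf_pairs <- hc$merge[hc$merge[, 1] < 0 & hc$merge[, 2] < 0, ,
                         drop = FALSE]
  merged <- apply(leaf_pairs, 1, function(r) {
    paste(sort(hc$labels[-r]), collapse = "\r")
  })
  wanted <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "\r"),
                   pairing$tumor_sample_id, pairing$healthy_sample_id)
  hit <- wanted %in% merged
  structure(mean(hit), paired_patients = pairing$patient_id[hit])
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on the differences `values_a - values_b` after dropping
#' zero differences: exact for up to 25 nonzero differences, otherwise the
#' normal approximation with tie correction (via [stats::wilcox.test()]).
#' The exact null distribution conditions on the observed absolute
#' differences — signs are flipped over all \eqn{2^n} assignments — and is
#' computed by dynamic programming over (doubled, hence integer) midranks,
#' so tied differences are handled exactly rather than forcing the
#' approximation. The reported statistic is centred (`V - n(n+1)/4`), so
#' swapping the two inputs flips its sign and leaves the p-value unchanged.
#'
#' @param values_a,values_b Equal-length numeric vectors (e.g. tumor and
#'   healthy measurements of the same patients).
#' @return List with `statistic` (centred signed-rank statistic), `p_value`,
#'   `n` (nonzero differences used), `exact`.
#' @export
paired_signed_rank <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("length mismatch")
  d <- values_a - values_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n < 5) stop("fewer than 5 nonzero differences (n = ", n, ")")
  ranks <- rank(abs(d))  # midranks under ties
  v_stat <- sum(ranks[d > 0])
  use_exact <- n <= 25
  if (use_exact) {
    ## distribution of 2*V over sign flips: DP over doubled midranks
    r2 <- as.integer(round(2 * ranks))
    total <- sum(r2)
    freq <- numeric(total + 1)  # freq[s + 1] ~ number of subsets with sum s
    freq[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), freq[seq_len(total + 1 - r)])
      freq <- freq + shifted
    }
    freq <- freq / 2^n
    w2 <- as.integer(round(2 * v_stat))
    p_lo <- sum(freq[seq_len(w2 + 1)])
    p_hi <- sum(freq[seq(w2 + 1, total + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                              correct = TRUE))
    p <- ht$p.value
  }
  list(statistic = v_stat - n * (n + 1) / 4,
       p_value = p, n = n, exact = use_exact)
}
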