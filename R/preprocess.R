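#' Apply limit-of-quantification censoring to a cytokine panel
#'
#' Values strictly below a cytokine's lower limit of quantification (LLOQ)
#' are set to 0 pg/ml and recorded in `censored_mask`, following the
#' immunoassay convention that sub-LLOQ readings are not quantifiable.
#' Values above the upper limit (ULOQ) are either clipped to the ULOQ or
#' left in place, and flagged either way.
#'
#' The operation is idempotent: censored zeros are below every LLOQ and stay
#' zero (and masked) on re-application.
#'
#' @param panel A [cytokine_panel()].
#' @param loq A [read_loq_table()] result covering every panel cytokine.
#' @param uloq_policy `"clip"` (replace by ULOQ) or `"flag"` (leave value).
#' @return The censored [cytokine_panel()].
#' @export
apply_loq <- function(panel, loq, uloq_policy = c("clip", "flag")) {
  uloq_policy <- match.arg(uloq_policy)
  stopifnot(inherits(panel, "cytokine_panel"))
  missing_cy <- setdiff(colnames(panel$values), loq$cytokine)
  if (length(missing_cy) > 0) {
    stop("no LOQ entry for cytokine(s): ", paste(missing_cy, collapse = ", "))
  }
  idx <- match(colnames(panel$values), loq$cytokine)
  lloq_row <- loq$lloq[idx]
  uloq_row <- loq$uloq[idx]
  vals <- panel$values
  below <- sweep(vals, 2, lloq_row, `<`)
  vals[below] <- 0
  above <- sweep(vals, 2, uloq_row, `>`)
  if (uloq_policy == "clip") {
    clipped <- sweep(vals, 2, uloq_row, pmin)
    vals <- clipped
  }
  cytokine_panel(vals,
                 censored_mask = below | panel$censored_mask,
                 uloq_flagged = above | panel$uloq_flagged)
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums counts across taxa sharing the same label at `rank`; taxa whose
#' lineage is "unclassified" at that rank are pooled into
#' `"unclassified_<rank>"`. Per-sample totals are conserved exactly.
#'
#' @param table An [otu_table()].
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return An [otu_table()] whose taxa are the distinct labels at `rank`.
#' @export
aggregate_to_rank <- function(table, rank) {
  stopifnot(inherits(table, "otu_table"))
  if (!rank %in% .tax_ranks) {
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(.tax_ranks, collapse = ", "))
  }
  labels <- table$taxonomy[[rank]]
  labels[is.na(labels) | labels == "" | labels == "unclassified"] <-
    paste0("unclassified_", rank)
  groups <- factor(labels, levels = unique(labels))
  agg <- t(rowsum(t(table$counts), group = groups))
  colnames(agg) <- levels(groups)
  ## lineage of an aggregate: ranks above `rank` kept when unanimous
  keep <- .tax_ranks[seq_len(match(rank, .tax_ranks))]
  tax <- data.frame(taxon_id = levels(groups), stringsAsFactors = FALSE)
  for (r in .tax_ranks) {
    if (r %in% keep && r != rank) {
      tax[[r]] <- vapply(levels(groups), function(g) {
        u <- unique(table$taxonomy[[r]][labels == g])
        if (length(u) == 1) u else "unclassified"
      }, character(1))
    } else if (r == rank) {
      tax[[r]] <- levels(groups)
    } else {
      tax[[r]] <- "unclassified"
    }
  }
  otu_table(agg, tax)
}

#' Build the top-k + residual composition response
#'
#' The `top_k` taxa with the largest total counts across samples become
#' named response categories; every other taxon is pooled into a final
#' `"residual"` category, so per-sample totals are partitioned, never
#' dropped. Ties in totals are broken lexicographically (and reported via a
#' message) for determinism.
#'
#' @param genus_table An [otu_table()], typically genus-aggregated.
#' @param top_k Number of named categories (default 3, giving a 4-category
#'   response).
#' @return Object of class `composition_response`: list with `counts`
#'   (samples x (top_k + 1) matrix) and `category_names` (last =
#'   `"residual"`).
#' @export
build_composition_response <- function(genus_table, top_k = 3) {
  stopifnot(inherits(genus_table, "otu_table"), top_k >= 1)
  totals <- colSums(genus_table$counts)
  nonzero <- totals[totals > 0]
  if (length(nonzero) < top_k + 1) {
    stop("need at least top_k + 1 = ", top_k + 1,
         " taxa with nonzero totals, found ", length(nonzero))
  }
  ord <- order(-nonzero, names(nonzero))
  if (anyDuplicated(nonzero[ord][seq_len(top_k + 1)]) > 0) {
    message("ties in top-", top_k, " totals broken lexicographically")
  }
  top <- names(nonzero)[ord][seq_len(top_k)]
  rest <- setdiff(colnames(genus_table$counts), top)
  counts <- cbind(genus_table$counts[, top, drop = FALSE],
                  residual = rowSums(genus_table$counts[, rest, drop = FALSE]))
  composition_response(counts)
}

#' Construct a composition response from a category count matrix
#'
#' @param counts Samples x J nonnegative integer matrix whose last column is
#'   the residual category.
#' @return Object of class `composition_response`.
#' @export
composition_response <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("category names required")
  if (any(counts < 0)) stop("negative category count")
  structure(list(counts = counts, category_names = colnames(counts)),
            class = "composition_response")
}

#' @export
print.composition_response <- function(x, ...) {
  cat("composition_response:", nrow(x$counts), "samples x",
      ncol(x$counts), "categories:",
      paste(x$category_names, collapse = ", "), "\n")
  invisible(x)
}

#' Build a standardized design matrix from a cytokine panel
#'
#' Prepends an intercept column of ones and applies the chosen columnwise
#' transform. The default `log1p_zscore` takes `log(1 + x)` before z-scoring
#' — Luminex concentrations are right-skewed over orders of magnitude and
#' would otherwise dominate the log link.
#'
#' @param panel A [cytokine_panel()] (or plain matrix with dimnames).
#' @param transform `"log1p_zscore"` (default), `"zscore"`, or `"none"`.
#' @return Object of class `design_matrix`: list with `X` (samples x (K+1),
#'   intercept first), `covariate_names`, `transform`.
#' @export
standardize_covariates <- function(panel,
                                   transform = c("log1p_zscore", "zscore",
                                                 "none")) {
  transform <- match.arg(transform)
  vals <- if (inherits(panel, "cytokine_panel")) panel$values else
    as.matrix(panel)
  z <- switch(transform,
    log1p_zscore = log1p(vals),
    zscore = vals,
    none = vals
  )
  if (transform != "none") {
    sds <- apply(z, 2, stats::sd)
    flat <- colnames(z)[sds == 0 | !is.finite(sds)]
    if (length(flat) > 0) {
      stop("zero-variance cytokine(s) under transform '", transform, "': ",
           paste(flat, collapse = ", "))
    }
    z <- scale(z)
  }
  X <- cbind(`(Intercept)` = 1, z)
  rownames(X) <- rownames(vals)
  structure(list(X = X, covariate_names = colnames(vals),
                 transform = transform),
            class = "design_matrix")
}
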