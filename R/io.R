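## Tabular I/O: counts/taxonomy/pairing as TSV, cytokines and LOQ as CSV.
## All readers expect UTF-8 with a mandatory header row; counts tables are
## samples-in-rows (first column = sample id) with a `transpose` switch for
## the taxa-in-rows dialect.

.tax_ranks <- c("phylum", "class", "order", "family", "genus")

#' Construct a validated OTU/taxon count table
#'
#' @param counts Nonnegative integer matrix, samples in rows, taxa in
#'   columns; dimnames give sample and taxon ids.
#' @param taxonomy Data frame with column `taxon_id` plus the ranked lineage
#'   columns phylum, class, order, family, genus (entries may be
#'   `"unclassified"`). Taxa present in `counts` but absent here are given an
#'   all-"unclassified" lineage with a warning.
#' @return Object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry sample ids (rownames) and taxon ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-integer count at sample '",
         rownames(counts)[bad[1, 1]], "', taxon '",
         colnames(counts)[bad[1, 2]], "' (value ",
         counts[bad[1, 1], bad[1, 2]], ")")
  }
  if (length(counts) == 0) stop("empty count table")
  storage.mode(counts) <- "double"

  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = colnames(counts))
    for (r in .tax_ranks) taxonomy[[r]] <- "unclassified"
  }
  if (!"taxon_id" %in% names(taxonomy)) stop("taxonomy needs a taxon_id column")
  missing_ranks <- setdiff(.tax_ranks, names(taxonomy))
  if (length(missing_ranks) > 0) {
    stop("taxonomy lacks rank column(s): ", paste(missing_ranks, collapse = ", "))
  }
  absent <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(absent) > 0) {
    warning(length(absent), " taxa missing from taxonomy; lineage set to ",
            "'unclassified': ", paste(utils::head(absent, 5), collapse = ", "))
    pad <- data.frame(taxon_id = absent)
    for (r in .tax_ranks) pad[[r]] <- "unclassified"
    taxonomy <- rbind(taxonomy[c("taxon_id", .tax_ranks)], pad)
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id),
                       c("taxon_id", .tax_ranks)]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa;",
      "total reads", sum(x$counts), "\n")
  invisible(x)
}

#' Read an OTU table and its taxonomy from TSV files
#'
#' @param counts_path TSV, samples in rows, first column the sample id
#'   (taxa in rows with `transpose = TRUE`).
#' @param taxonomy_path TSV with columns taxon_id, phylum, class, order,
#'   family, genus. `NULL` assigns "unclassified" lineages.
#' @param transpose Set when the counts file has taxa in rows.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(counts_path, taxonomy_path = NULL,
                           transpose = FALSE) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty count table: ", counts_path)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", counts_path)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    taxonomy <- utils::read.delim(taxonomy_path, check.names = FALSE,
                                  stringsAsFactors = FALSE,
                                  fileEncoding = "UTF-8")
  }
  otu_table(m, taxonomy)
}

#' Write an OTU table (and optionally its taxonomy) to TSV
#'
#' Emits the same samples-in-rows dialect [read_otu_table()] accepts, so a
#' write/read round trip reproduces counts exactly.
#'
#' @param table An [otu_table()].
#' @param counts_path,taxonomy_path Output TSV paths (`taxonomy_path` may be
#'   `NULL`).
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path = NULL) {
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(taxonomy_path)) {
    utils::write.table(table$taxonomy, taxonomy_path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(counts_path)
}

#' Construct a cytokine panel
#'
#' @param values Matrix of concentrations in pg/ml, samples in rows,
#'   cytokines in columns (dimnames mandatory).
#' @param censored_mask Logical matrix marking values set to 0 by the LLOQ
#'   rule; defaults to all-FALSE (censoring not yet applied).
#' @param uloq_flagged Logical matrix marking values above the ULOQ.
#' @return Object of class `cytokine_panel`.
#' @export
cytokine_panel <- function(values, censored_mask = NULL, uloq_flagged = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and cytokine names")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate cytokine names")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("negative concentration")
  if (is.null(censored_mask)) {
    censored_mask <- matrix(FALSE, nrow(values), ncol(values),
                            dimnames = dimnames(values))
  }
  if (is.null(uloq_flagged)) {
    uloq_flagged <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  }
  stopifnot(identical(dim(censored_mask), dim(values)),
            identical(dim(uloq_flagged), dim(values)))
  structure(list(values = values, censored_mask = censored_mask,
                 uloq_flagged = uloq_flagged),
            class = "cytokine_panel")
}

#' @export
print.cytokine_panel <- function(x, ...) {
  cat("cytokine_panel:", nrow(x$values), "samples x", ncol(x$values),
      "cytokines (pg/ml);", sum(x$censored_mask), "values censored to 0\n")
  invisible(x)
}

#' Read a cytokine panel from CSV (samples x cytokines, pg/ml)
#' @param path CSV with first column the sample id.
#' @return A [cytokine_panel()].
#' @export
read_cytokine_panel <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  cytokine_panel(m)
}

#' Write a cytokine panel to CSV
#' @param panel A [cytokine_panel()].
#' @param path Output CSV path.
#' @export
write_cytokine_panel <- function(panel, path) {
  df <- data.frame(sample_id = rownames(panel$values), panel$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a limit-of-quantification table
#'
#' The package ships the 26-cytokine Luminex panel limits as
#' `system.file("extdata", "cytokine_loq.csv", package = "cytotaxa")`
#' (decimal commas of the source normalized to points).
#'
#' @param path CSV with columns cytokine, uloq_pg_ml, lloq_pg_ml. Default:
#'   the packaged panel.
#' @return Data frame of class `loq_table` with columns cytokine, lloq, uloq.
#' @export
read_loq_table <- function(path = system.file("extdata", "cytokine_loq.csv",
                                              package = "cytotaxa")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  out <- data.frame(cytokine = raw$cytokine, lloq = raw$lloq_pg_ml,
                    uloq = raw$uloq_pg_ml, stringsAsFactors = FALSE)
  if (any(!(out$lloq > 0 & out$lloq < out$uloq))) {
    stop("LOQ table must satisfy 0 < LLOQ < ULOQ for every cytokine")
  }
  if (anyDuplicated(out$cytokine)) stop("duplicate cytokine in LOQ table")
  class(out) <- c("loq_table", "data.frame")
  out
}

#' Construct a patient-to-sample pairing table
#'
#' @param patient_id,tumor_sample_id,healthy_sample_id Equal-length vectors;
#'   every sample id must be distinct.
#' @return Data frame of class `sample_pairing`.
#' @export
sample_pairing <- function(patient_id, tumor_sample_id, healthy_sample_id) {
  df <- data.frame(patient_id = as.character(patient_id),
                   tumor_sample_id = as.character(tumor_sample_id),
                   healthy_sample_id = as.character(healthy_sample_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient id")
  ids <- c(df$tumor_sample_id, df$healthy_sample_id)
  if (anyDuplicated(ids)) stop("sample ids in pairing must be distinct")
  class(df) <- c("sample_pairing", "data.frame")
  df
}

#' Read a pairing table from TSV (patient_id, tumor_sample_id,
#' healthy_sample_id)
#' @param path TSV path.
#' @return A [sample_pairing()].
#' @export
read_sample_pairing <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  sample_pairing(raw$patient_id, raw$tumor_sample_id, raw$healthy_sample_id)
}

#' Write a pairing table to TSV
#' @param pairing A [sample_pairing()].
#' @param path Output path.
#' @export
write_sample_pairing <- function(pairing, path) {
  utils::write.table(as.data.frame(pairing), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
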