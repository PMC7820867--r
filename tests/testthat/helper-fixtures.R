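## Shared fixtures, all built in code.

## tiny OTU table: 2 samples x 3 OTUs with a genus-level taxonomy
toy_otu <- function() {
  m <- matrix(c(1, 2, 3,
                4, 5, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("OTU1", "OTU2", "OTU3")))
  tax <- data.frame(
    taxon_id = c("OTU1", "OTU2", "OTU3"),
    phylum = c("Bacteroidetes", "Bacteroidetes", "Proteobacteria"),
    class = "unclassified", order = "unclassified", family = "unclassified",
    genus = c("Prevotella", "Prevotella", "Escherichia/Shigella"),
    stringsAsFactors = FALSE)
  otu_table(m, tax)
}

write_toy_tsvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tab <- toy_otu()
  cp <- file.path(dir, "counts.tsv")
  tp <- file.path(dir, "taxonomy.tsv")
  write_otu_table(tab, cp, tp)
  list(counts = cp, taxonomy = tp, table = tab)
}

## direct gamma-function product oracle for the DM pmf (independent of the
## lgamma-sum implementation): N! / prod(n_j!) * G(A)/G(N+A) *
## prod G(n_j + a_j)/G(a_j), evaluated with gamma() and factorial()
dm_pmf_gamma_oracle <- function(counts, alpha) {
  n_tot <- sum(counts)
  a_tot <- sum(alpha)
  factorial(n_tot) / prod(factorial(counts)) *
    gamma(a_tot) / gamma(n_tot + a_tot) *
    prod(gamma(counts + alpha) / gamma(alpha))
}

## all nonnegative integer J-vectors summing to N
enumerate_counts <- function(n_tot, j_dim) {
  if (j_dim == 1) return(matrix(n_tot, 1, 1))
  out <- NULL
  for (first in 0:n_tot) {
    rest <- enumerate_counts(n_tot - first, j_dim - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

## Dirichlet proportions via normalized gammas
rdirichlet_rows <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  g / rowSums(g)
}

## small synthetic study restricted to one tissue, as (panel, response)
tumor_slice <- function(study) {
  ids <- study$pairing$tumor_sample_id
  list(
    panel = cytokine_panel(
      study$cytokine_panel_censored$values[ids, , drop = FALSE]),
    response = composition_response(
      study$composition$counts[ids, , drop = FALSE]),
    ids = ids)
}
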