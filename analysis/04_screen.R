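#!/usr/bin/env Rscript
## Step 1 of the association analysis: sure-independence screening. Each
## cytokine alone predicts the 4-category composition in a log-link
## Dirichlet regression; a likelihood-ratio test against the intercept-only
## model (df = 4) yields the ranking p-value. Run separately per tissue,
## as the full analysis is tissue-stratified.
##
## Reads results/study/ + results/composition_*.csv, writes
## results/screening_{tumor,healthy}.csv.

library(cytotaxa)

panel <- read_cytokine_panel("results/cytokines_censored.csv")
pairing <- read_sample_pairing("results/study/pairing.tsv")

for (tissue in c("tumor", "healthy")) {
  comp <- utils::read.csv(sprintf("results/composition_%s.csv", tissue),
                          check.names = FALSE, fileEncoding = "UTF-8")
  counts <- as.matrix(comp[, -1])
  rownames(counts) <- comp$sample_id
  sub_panel <- cytokine_panel(panel$values[comp$sample_id, , drop = FALSE])
  scr <- screen_cytokines(sub_panel, composition_response(counts),
                          top_m = 3)
  cat("\n--", tissue, "screen --\n")
  print(scr)
  utils::write.csv(scr$table, sprintf("results/screening_%s.csv", tissue),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}
cat("\np-values are used for ranking only (no multiplicity correction).\n")
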