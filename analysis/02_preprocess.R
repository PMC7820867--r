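#!/usr/bin/env Rscript
## Preprocess the study tables: LLOQ-censor the cytokine panel (sub-LLOQ
## values become 0 pg/ml, over-ULOQ values are clipped and flagged),
## aggregate OTUs to genus, and build the per-tissue 4-category composition
## responses (top-3 genera + residual).
##
## Reads results/study/, writes results/composition_{tumor,healthy}.csv and
## results/cytokines_censored.csv.

library(cytotaxa)

otu <- read_otu_table("results/study/counts.tsv",
                      "results/study/taxonomy.tsv")
panel <- read_cytokine_panel("results/study/cytokines.csv")
pairing <- read_sample_pairing("results/study/pairing.tsv")
loq <- read_loq_table()

cens <- apply_loq(panel, loq, uloq_policy = "clip")
cat(sum(cens$censored_mask), "of", length(cens$values),
    "cytokine values censored to 0 (below LLOQ);",
    sum(cens$uloq_flagged), "clipped at ULOQ\n")
write_cytokine_panel(cens, "results/cytokines_censored.csv")

genus <- aggregate_to_rank(otu, "genus")
cat("genus table:", ncol(genus$counts), "genera from",
    ncol(otu$counts), "OTUs; per-sample totals conserved:",
    all(rowSums(genus$counts) == rowSums(otu$counts)), "\n")

for (tissue in c("tumor", "healthy")) {
  ids <- if (tissue == "tumor") pairing$tumor_sample_id else
    pairing$healthy_sample_id
  sub <- otu_table(genus$counts[ids, , drop = FALSE], genus$taxonomy)
  resp <- build_composition_response(sub, top_k = 3)
  cat(tissue, "response categories:",
      paste(resp$category_names, collapse = ", "), "\n")
  utils::write.csv(data.frame(sample_id = ids, resp$counts,
                              check.names = FALSE),
                   sprintf("results/composition_%s.csv", tissue),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}
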