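#!/usr/bin/env Rscript
## Collate the diversity summary, screening tables and association tables
## into a single plain-text report: results/report.txt.

library(cytotaxa)

path <- make_report("results")
cat("report written to", path, "\n")
cat(readLines(path, n = 15), sep = "\n")
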