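#!/usr/bin/env Rscript
# Stage 4: two-set consensus modules and eigengene-network preservation.
#
# Rebuilds the network independently in each cohort, quantile-scales the
# second TOM onto the first, takes the elementwise minimum and detects
# consensus modules with the same parameters as the merged run. The
# consensus module-trait table keeps, per module, the weaker same-sign
# correlation of the two cohorts (NA when the cohorts disagree in sign),
# and the preservation report compares the two eigengene networks.

suppressMessages(library(coexmod))

set1 <- read_expression("results/data/set1_expression.tsv",
                        "results/data/set1_samples.tsv")
set2 <- read_expression("results/data/set2_expression.tsv",
                        "results/data/set2_samples.tsv")
part <- read.delim("results/merged/module_partition.tsv")
merged_labels <- setNames(as.integer(part$module), part$gene)

rep <- run_consensus_workflow(set1, set2, "results/consensus",
                              merged_labels = merged_labels,
                              power = 6, seed = 1)
print(rep)
cat("\nconsensus module-trait table:\n")
print(rep$consensus_trait, digits = 3)

cat("\nper-eigengene mean preservation:\n")
print(round(rep$preservation$per_eigengene, 3))

ov <- rep$overlap$counts
cat("\nconsensus (rows) vs merged-run (columns) overlap counts:\n")
print(ov)
diag_frac <- sapply(setdiff(rownames(ov), "0"), function(r)
  max(ov[r, ]) / sum(ov[r, ]))
cat("fraction of each consensus module in its best merged module:",
    paste(round(diag_frac, 2), collapse = " "), "\n")
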