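#!/usr/bin/env Rscript
# Stage 3: relate modules to the case/control trait and rank hub genes.
#
# Uses the tables written by 02_merged_network.R. The module whose
# eigengene has the largest absolute correlation with the case indicator
# is reported as the trait module; its module-membership/gene-significance
# coupling and its top-30 intramodular-connectivity hubs are summarized.

suppressMessages(library(coexmod))

mt <- read.delim("results/merged/module_trait.tsv")
gs <- read.delim("results/merged/gene_stats.tsv")
hubs <- read.delim("results/merged/hub_genes.tsv")

cat("module-trait correlations (case indicator):\n")
print(mt[, c("module", "r_case", "p_case", "ms_trait")], digits = 3)

flagged <- mt$module[mt$ms_trait]
flag_id <- as.integer(sub("ME", "", flagged))
cat("\ntrait module:", flagged,
    sprintf("(r = %.3f, p = %.3g)\n",
            mt$r_case[mt$ms_trait], mt$p_case[mt$ms_trait]))

mmgs <- mm_gs_module_summary(gs, flag_id)
cat(sprintf("MM-GS coupling in %s: cor = %.3f, p = %.3g\n",
            flagged, mmgs$r, mmgs$p))

top <- hubs[hubs$module == flag_id, ]
cat("\ntop-10 hub genes of the trait module (by intramodular connectivity):\n")
print(head(top$gene, 10))
write.table(top, "results/merged/trait_module_hubs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
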