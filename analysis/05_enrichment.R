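#!/usr/bin/env Rscript
# Stage 5: hypergeometric over-representation of the trait-module genes.
#
# In a real study the collection would be GO/KEGG gene sets in GMT format;
# here the planted modules serve as the gene-set collection (plus random
# decoy sets), so the expected outcome is known: the trait module's genes
# and hubs should be over-represented in their planted set and nowhere
# else (Bonferroni threshold 1e-4).

suppressMessages(library(coexmod))

part <- read.delim("results/merged/module_partition.tsv")
mt <- read.delim("results/merged/module_trait.tsv")
hubs <- read.delim("results/merged/trait_module_hubs.tsv")
truth <- read.delim("results/data/ground_truth.tsv")

universe <- part$gene
collection <- split(truth$gene, truth$module)
names(collection) <- ifelse(names(collection) == "0", "background",
                            paste0("planted_module_", names(collection)))
set.seed(1)
for (i in 1:3)
  collection[[paste0("decoy_", i)]] <- sample(truth$gene, 150)

# write the collection as GMT and read it back (the real-data entry path)
gmt <- "results/enrichment_sets.gmt"
dir.create("results", showWarnings = FALSE)
writeLines(vapply(names(collection), function(nm)
  paste(c(nm, "synthetic set", collection[[nm]]), collapse = "\t"), ""), gmt)
collection <- read_gmt(gmt)

flag_id <- as.integer(sub("ME", "", mt$module[mt$ms_trait]))
query_module <- part$gene[part$module == flag_id]

res_module <- hypergeometric_ora(query_module, collection, universe)
cat("ORA of the trait module's genes:\n")
print(res_module[, c("set", "k", "K", "p", "p_bonferroni", "significant")],
      digits = 3)

res_hubs <- hypergeometric_ora(hubs$gene, collection, universe)
cat("\nORA of the trait module's top-30 hubs:\n")
print(res_hubs[, c("set", "k", "K", "p", "p_bonferroni", "significant")],
      digits = 3)

write.table(res_module, "results/enrichment_trait_module.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res_hubs, "results/enrichment_trait_hubs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
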