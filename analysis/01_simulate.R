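#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-cohort study.
#
# Two case/control blood-expression cohorts (17/30 and 21/59 samples, the
# design of the sJIA microarray study this workflow follows), five planted
# coexpression modules (300/200/150/100/60 genes) driven by latent factors,
# a 1.5-SD case shift on the largest module's factor, 2,000 background
# genes, unit noise and additive per-cohort batch effects (SD 1, log2
# scale). Ground truth is written next to the data so later stages can be
# scored.

suppressMessages(library(coexmod))

out <- "results/data"
cfg <- sim_config(seed = 1)
sim <- simulate_pair(cfg)
write_simulation(sim, out)

cat("cohort 1:", ncol(sim$set1$values), "samples;",
    "cohort 2:", ncol(sim$set2$values), "samples;",
    nrow(sim$set1$values), "shared genes\n")
cat("planted modules:", paste(cfg$module_sizes, collapse = "/"),
    "genes; trait effect", cfg$trait_effect_sizes[1],
    "latent SD on module 1\n")
cat("written to", out, "\n")
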