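Package: coexmod
Title: Weighted Gene Coexpression Modules for Two-Cohort Case/Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted gene coexpression network analysis for merged and
    two-set consensus case/control expression studies. Implements the full
    chain from normalized expression matrices to trait-related modules:
    probe collapse, empirical-Bayes batch adjustment, variance filtering,
    soft-threshold selection by scale-free topology fit, unsigned
    topological overlap, average-linkage clustering with an adaptive tree
    cut, module eigengenes and eigengene-based module merging, module-trait
    correlation, intramodular-connectivity hub ranking, two-set consensus
    modules with eigengene-network preservation statistics, and
    hypergeometric over-representation analysis against user-supplied gene
    set collections. Ships a seeded two-cohort simulator with planted
    modules, trait effects and batch effects so every stage is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    sva
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
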