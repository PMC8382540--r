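# coexmod

Weighted gene coexpression network analysis (WGCNA) for two-cohort
case/control expression studies, implemented as a tested R package plus a
numbered analysis workflow.

## The problem

Case/control transcriptomics of rare diseases — the motivating setting is
systemic juvenile idiopathic arthritis (sJIA) blood microarrays, with two
public cohorts of 17 case / 30 control and 21 case / 59 control samples —
rarely has the power for gene-by-gene testing. Coexpression network
analysis instead groups genes into modules of mutually correlated
expression, relates each module's summary profile to disease status, and
ranks each module's most connected (hub) genes as candidate biomarkers.
`coexmod` implements that full chain for a merged two-cohort analysis and
for a two-set consensus analysis that checks the modules replicate across
cohorts:

* preprocessing: log2 scale, multi-gene probe removal with max-mean probe
  collapse, empirical-Bayes batch adjustment (ComBat, case/control
  protected), top-25% variance filtering;
* network: Pearson correlation, unsigned soft-thresholded adjacency
  `a_ij = |cor_ij|^β`, scale-free topology scan over powers 1–20,
  topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij) /
  (min(k_i,k_j) + 1 − a_ij)`;
* modules: average-linkage clustering of `1 − TOM`, dynamic tree cut
  (minimum module size 40), module eigengenes (first principal
  components), merging of modules whose eigengenes correlate above 0.75;
* trait statistics: module–trait correlation with Student-t p-values,
  gene significance (GS), module membership (kME), intramodular
  connectivity and top-30 hub lists;
* consensus: quantile-scaled elementwise-minimum consensus TOM, consensus
  modules, the weaker-same-sign/NA-on-disagreement consensus trait rule,
  and eigengene-network preservation
  `1 − |A⁽¹⁾ − A⁽²⁾|`, `A_ij = (1 + cor(ME_i, ME_j))/2`;
* enrichment: hypergeometric over-representation against a GMT gene-set
  collection with Bonferroni control at 1e-4.

Real cohorts are external downloads, so the package ships a seeded
two-cohort simulator with planted modules, trait effects and batch
effects; the analysis scripts and the acceptance run score the pipeline
against that planted ground truth. See the methods vignette
(`vignettes/coexpression-methods.Rmd`) for the model, parameter
rationale, and design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # two cohorts + ground truth
Rscript analysis/02_merged_network.R  # merged network and modules
Rscript analysis/03_trait_modules.R   # module-trait table, hubs
Rscript analysis/04_consensus.R       # consensus modules, preservation
Rscript analysis/05_enrichment.R      # hypergeometric ORA
```

Stage 2 merges the cohorts, adjusts the batch effect, filters to the top
25% most variable genes and detects modules at power 6:

```
genes after variance filter: 703 of 2810
modules detected: 5 ( 5 before eigengene merging ); 10 genes unassigned
module sizes: 255/174/125/88/51
adjusted Rand index vs planted truth: 1
```

The five planted modules are recovered exactly (adjusted Rand index 1
against the planted partition, computed over all analyzed genes). Stage 3
relates module eigengenes to the case indicator:

```
  module   r_case   p_case ms_trait
1    ME1  0.60716 3.81e-14     TRUE
2    ME2 -0.08810 3.25e-01    FALSE
3    ME3 -0.00357 9.68e-01    FALSE
4    ME4  0.16585 6.24e-02    FALSE
5    ME5  0.05903 5.10e-01    FALSE

trait module: ME1 (r = 0.607, p = 3.81e-14)
MM-GS coupling in ME1: cor = 0.555, p = 5.26e-22
```

ME1 — the module carrying the planted 1.5-SD trait effect — is flagged as
the disease module (largest |r|), and within it module membership and
gene significance are strongly coupled, the signature of a genuinely
trait-driven module. Stage 4 verifies the result replicates across the
two cohorts analyzed independently:

```
consensus_report: 703 genes, 5 consensus modules
  eigengene-network preservation density: 0.928264
  consensus trait table NA cells: 2/5
fraction of each consensus module in its best merged module: 1 0.99 1 0.98 1
```

The two cohorts' eigengene networks agree with preservation density 0.93,
and every consensus module maps almost entirely onto one merged-run
module. Stage 5 confirms the trait module's top-30 hubs are
over-represented in their planted set (`p_bonferroni = 1.75e-13`) and in
none of the decoy sets.

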