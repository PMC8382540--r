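---
title: "Weighted coexpression modules for two-cohort case/control studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted coexpression modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

## The analysis this package implements

`coexmod` reimplements, as tested and reusable functions, the complete
weighted gene coexpression network analysis (WGCNA) chain used to find
disease-associated transcriptional modules in merged case/control
microarray cohorts: preprocessing (log2 scale, probe collapse,
empirical-Bayes batch adjustment, top-variance filtering), unsigned
network construction with soft thresholding, topological-overlap
clustering with a dynamic tree cut, module eigengenes and module merging,
module–trait statistics and hub-gene ranking, a two-set consensus
analysis with eigengene-network preservation, and hypergeometric
over-representation analysis against user-supplied gene sets. The
motivating application is systemic juvenile idiopathic arthritis (sJIA)
blood expression, with two public cohorts of 17 case / 30 control and
21 case / 59 control samples; every stage, however, is generic.

Because the original cohorts are external downloads, the package ships a
seeded simulator whose defaults emulate that study design, so the whole
chain can be exercised and scored against planted ground truth.

## The network model

For genes $i,j$ with expression correlation $r_{ij}$ across samples, the
unsigned adjacency is

$$a_{ij} = |r_{ij}|^\beta,$$

with the soft-thresholding power $\beta$ chosen so that connectivity
$k_i = \sum_{j \ne i} a_{ij}$ approximately follows a power law
(scale-free topology). The topological overlap similarity is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

and $1 - \mathrm{TOM}$ is the clustering dissimilarity. Modules are
branches of the average-linkage dendrogram; each module is summarized by
its eigengene (first principal component of the standardized module
expression), and modules whose eigengenes correlate above
$1 - \text{mergeCutHeight} = 0.75$ are merged. Module–trait association
is the Pearson correlation between an eigengene and the binary case
indicator, with a Student-$t$ p-value on $n-2$ degrees of freedom
computed through the regularized incomplete beta function. Gene
significance (GS) is the gene–trait correlation, module membership (kME)
the gene–eigengene correlation, and hub genes are the top 30 genes of a
module by intramodular connectivity
$k^{IN}_i = \sum_{j \in \text{module}(i)} a_{ij}$.

### Scale-free fit and power selection

The fit index bins $k$ into 10 equal-width bins and regresses
$\log_{10}$ frequency on $\log_{10}$ mean connectivity over non-empty
bins; the returned index is $R^2$ signed by $-\mathrm{sign}(\text{slope})$.
`pick_soft_threshold()` scans powers 1–20 and picks the smallest power
whose signed fit reaches `target_r2` (default 0.85), falling back to the
argmax. Both the bin count and the criterion are configurable because the
methodological literature fixes neither.

The workflow scripts and the acceptance run use $\beta = 6$, the power
the motivating study selected for its 5,414-gene blood dataset, rather
than the scan's choice. On the synthetic data the scan settles around
10–11: after the top-25% variance filter almost every retained gene
belongs to a planted module (module genes have strictly higher population
variance than the uniform background under the factor model), so the
network lacks the large weakly-connected bulk of real expression data and
needs a higher power to look scale-free. This is a property of the
simulation's sharply two-class variance structure, not of the method; the
scan's selection contract is tested separately.

## The synthetic study design

`sim_config()` defaults encode the study conditions: two cohorts of
17/30 and 21/59 case/control samples, five planted modules of
300/200/150/100/60 genes, 2,000 background genes, unit residual noise,
and a trait effect of 1.5 latent-SD on the largest module. Gene $g$ in
module $m$ follows

$$x_{gs} = \lambda_g u_m(s) + \varepsilon_{gs},$$

where $u_m$ is a standardized latent factor (shifted upward in cases by
the module's trait effect before standardization), loadings $\lambda_g$
are uniform on $[0.6, 0.95]$, and $\varepsilon_{gs} \sim N(0, \sigma^2)$.
Two genes in one module then have population correlation
$\lambda_1\lambda_2 / \sqrt{(\lambda_1^2+\sigma^2)(\lambda_2^2+\sigma^2)}$
(about 0.25–0.45 at the defaults), a realistic within-module range for
blood microarrays. Each cohort receives an additive per-gene batch shift
$\gamma_{gb} \sim N(0, 1)$ on the log2 scale — the magnitude of
cross-GEO-series offsets — plus a constant baseline of 8 so values sit in
a plausible log2-intensity range; a multiplicative batch-scale option and
an inter-module factor-correlation option (for exercising module
merging) are off by default. The loading range and batch SD are the
package's own realism choices; sample sizes, module floor, noise level
and the 1.5-SD effect follow the study design.

What the simulator does *not* emulate: probe-level intensity artifacts,
mean–variance coupling, heavy-tailed expression, correlated background
structure (cell-type composition), or RNA-seq counts. Passing tests
therefore demonstrate correctness of the pipeline's computations and its
behavior under the factor-model idealization, not performance on real
arrays.

## Preprocessing choices

* **log2**: `log2(x + 1)`, auto-skipped when the matrix maximum is below
  30 (already-logged data).
* **Probe collapse**: probes annotated to more than one gene are
  eliminated; among a gene's remaining probes the row with the largest
  mean expression is kept whole ("MaxMean" row selection). Elementwise
  maxima across probes are deliberately not taken — mixing probes within
  a row would fabricate expression profiles.
* **Batch adjustment**: parametric empirical-Bayes location/scale
  adjustment (ComBat, via the sva package) with the case/control contrast
  protected as a model covariate so the trait signal is not absorbed into
  the batch term; when the contrast is confounded with batch (each batch
  single-group) there is nothing to protect and the covariate is dropped.
  A single batch returns the input unchanged.
* **Variance filter**: keeps `ceiling(fraction * n)` genes (default
  fraction 0.25), ties at the cutoff broken by gene id ascending —
  `ceiling` and the id tie-break make the gene set deterministic.

## Module detection: the tree cut

The dynamic cut is implemented as a tree-variant branch decomposition
(no per-gene PAM stage). Conceptually it breaks dendrogram merges in
decreasing height order: wherever both sub-branches hold at least
`min_module_size` (default 40) genes the tree splits and each side is
decomposed recursively; loose genes and undersized branches chained onto
the top of a branch are shed as unassigned along the way. A branch that
never splits is a candidate module and is kept whole unless a dominant
gap in its merge-height spectrum separates a tight core from loosely
attached material. The gap is assessed on the log scale of *merge
similarity* (headroom below the tree's top height) because topological
overlap compresses dissimilarities toward 1 — junk attaches with several-
fold less headroom than a core's own merges, while a homogeneous branch
has a continuous spectrum and shows no such fold-change (`gap_fold`,
default 4). A simple static cut at a fixed height quantile was evaluated
first and rejected: on consensus dendrograms two genuine modules can join
*below* the global cut level (loose-gene merges occupy the top heights),
and no single global height both separates modules and sheds the loose
chain.

Two consequences are worth knowing. Large homogeneous modules may split
into several branches at this stage; the eigengene-merge step (average
linkage on $1 - \mathrm{cor}(\mathrm{ME})$, cut at 0.25, iterated to a
fixed point) reunites them, which is exactly the division of labor in
standard WGCNA practice. And background genes that correlate with a
module's latent factor by sampling accident (inevitable at
$n \approx 50$–130) attach to that module rather than to the grey set;
without a PAM-style reassignment stage — deliberately out of scope — the
cut cannot adjudicate them.

Module labels are re-ranked by decreasing size after every labeling
operation and mapped to the standard WGCNA color vocabulary (turquoise,
blue, brown, ... ), so "red" or "greenyellow" are meaningful names in
reports. Eigengene signs are aligned to the module's mean expression
profile, removing the SVD sign ambiguity and making module–trait signs
reproducible; eigengene rows are unit-norm.

## Trait statistics

GS is stored *signed* with the absolute view derivable: the classical
definition is absolute, but a negative MM–GS correlation (which the
motivating study itself reports for one module) is only expressible with
signs. The trait enters once as the binary case indicator; the control
column of the module–trait table is its exact negation. The module with
the largest $|r|$ carries the module-significance flag and is the module
taken forward for hub analysis and enrichment. P-values are reported
exactly, floored only at the smallest representable double, and no
multiple-testing correction is applied to module–trait tables (none is
standard there); enrichment, by contrast, is Bonferroni-controlled at
1e-4 over the sets tested. Hub ties (equal intramodular connectivity)
break by gene id ascending.

## Consensus analysis

Per-set TOMs are built at a common power; the second TOM is mapped by the
power transform `tom_b ^ (log q_a / log q_b)` so its 95th off-diagonal
percentile matches the first's (monotone, hence order-preserving), and
the consensus TOM is the elementwise minimum — the established convention
where the combining rule is not otherwise specified. Scaling is a flag
(`scale_toms`) because it carries a real trade-off: matching the upper
quantiles also raises the noisier set's background floor, and for a
module present in only one set the minimum of (strong, floor) then
stochastically exceeds the minimum of two independent floor draws, so a
fraction of one-set-module genes can re-cluster in the consensus. With
scaling off, such genes go cleanly to grey; at the network level their
consensus TOM collapses to within a few-fold of the background floor
either way (two orders of magnitude below intact modules), and the test
suite pins both behaviors.

Consensus module merging uses the componentwise *minimum* of the two
sets' eigengene correlation matrices, mirroring the TOM rule. The
consensus module–trait table keeps, per module, the same-sign correlation
of smaller magnitude with the larger p-value, and NA where the cohorts
disagree in sign. Eigengene-network preservation between sets is
$1 - |A^{(1)} - A^{(2)}|$ with $A^{(s)}_{ij} = (1 + \mathrm{cor}(ME_i,
ME_j))/2$; its mean over distinct pairs is the preservation density.
Gene universes are intersected (not unioned) before consensus — the
minimum is undefined for genes absent from one set — and the shared
variance filter ranks genes by the mean of per-set variances so both
sets retain an identical gene set.

## Enrichment

Over-representation of a query list in a gene set is the hypergeometric
upper tail $P(X \ge k)$ with the universe as background; sets are
intersected with the universe first (genes outside it are dropped and
counted), only enrichment is tested (the motivating analysis never
reports depletion), and Bonferroni multiplies by the number of sets
tested. Collections arrive as standard GMT.

## Numerical and determinism choices

* All randomness flows from one integer seed in `sim_config()`; the
  analysis chain itself (ComBat, SVD, hclust, cutree) is deterministic,
  so two runs from one seed are byte-identical — a tested property.
* Output tables are TSV with 6-significant-digit floats for diff-able
  reruns; manifests record parameters, seed, and per-stage row counts.
* Correlation p-values go through `pbeta` directly
  ($p = I_{1-r^2}(\tfrac{df}{2}, \tfrac12)$), cross-checked against
  numeric quadrature of the $t$ density to six significant figures.
* The dense single-block implementation guards at 6,000 genes (the
  block-size ceiling of the motivating analysis) and errors above it
  rather than silently preclustering; the study-scale dataset (5,414
  genes) fits one block.
* Degenerate inputs fail loudly with the offending gene/sample named:
  zero-variance genes, missing annotation, non-numeric cells, batches
  with fewer than two samples, empty collapse results.

## Problem sizes used in testing

The unit suite runs mostly on a reduced design (three modules of
60/50/40 genes, 300 background genes, two cohorts of 25–60 samples) so
the whole suite completes in well under a minute; the end-to-end
behavioral checks and the acceptance script run the full study-scale
default (2,810 genes simulated, 703 analyzed after filtering, 127
samples) where module recovery is scored against planted truth
(adjusted Rand index ≈ 0.99–1.0 at power 6, preservation density ≈ 0.93,
the planted trait module flagged with $r \approx 0.6$). Statistical
property tests (permutation p-values, factor-model closed forms,
overlap-p uniformity) use fixtures sized so their sampling error is well
inside the asserted tolerances.

## Known limitations

* No PAM stage and no kME-based reassignment: grey-zone genes stay where
  the dendrogram puts them.
* Unsigned networks only; signed and signed-hybrid variants, biweight
  midcorrelation, and sparse TOM approximations are out of scope.
* Exactly two sets in the consensus; no permutation-based Z-summary
  module preservation.
* The module count of any real dataset depends on tree-cut defaults that
  published analyses rarely report; matching a published module count
  exactly is therefore not a supported target, and the package is scored
  on planted-truth recovery instead.
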