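#' Quantile-scale a second TOM onto the first
#'
#' Applies the power transform `tom_b ^ (log q_a / log q_b)` where `q_a`,
#' `q_b` are the given upper quantiles of the off-diagonal TOM values, so
#' the two TOM value distributions match at that quantile before the
#' elementwise-minimum consensus is taken. The map is monotone, so the
#' within-set ordering of topological overlaps is preserved.
#'
#' @param tom_a,tom_b TOM matrices over the same genes.
#' @param quantile Off-diagonal quantile to match (default 0.95).
#' @return The scaled `tom_b`.
#' @export
scale_second_tom <- function(tom_a, tom_b, quantile = 0.95) {
  stopifnot(all(dim(tom_a) == dim(tom_b)))
  off <- upper.tri(tom_a)
  q_a <- stats::quantile(tom_a[off], quantile, names = FALSE)
  q_b <- stats::quantile(tom_b[off], quantile, names = FALSE)
  if (q_a <= 0 || q_a >= 1 || q_b <= 0 || q_b >= 1)
    stop("degenerate TOM quantile (0 or 1); cannot scale")
  out <- tom_b^(log(q_a) / log(q_b))
  diag(out) <- 1
  out
}

#' Elementwise-minimum consensus TOM
#'
#' @param tom_a,tom_b TOM matrices with identical gene ids in identical
#'   order.
#' @return `pmin(tom_a, tom_b)`.
#' @export
consensus_tom <- function(tom_a, tom_b) {
  if (!identical(dimnames(tom_a), dimnames(tom_b)))
    stop("TOM gene ids are misaligned")
  pmin(tom_a, tom_b)
}

#' Consensus module-trait correlation rule
#'
#' Two per-set correlations with the same sign are summarized by the one
#' with the smaller absolute value (the conservative choice), paired with
#' the larger of the two p-values; opposite signs (or one zero against a
#' nonzero) yield no consensus (NA). Vectorized over its inputs.
#'
#' @param r1,p1,r2,p2 Per-set correlation and p-value vectors.
#' @return Data frame with columns `r` and `p` (NA where no consensus).
#' @export
consensus_trait_relation <- function(r1, p1, r2, p2) {
  same_sign <- sign(r1) == sign(r2) & sign(r1) != 0
  pick_first <- abs(r1) <= abs(r2)
  r <- ifelse(same_sign, ifelse(pick_first, r1, r2), NA_real_)
  p <- ifelse(same_sign, pmax(p1, p2), NA_real_)
  data.frame(r = r, p = p)
}

#' Eigengene-network preservation between two datasets
#'
#' Each dataset's eigengene network is `A(i, j) = (1 + cor(ME_i, ME_j)) / 2`;
#' the preservation network is `1 - |A_a - A_b|`. Per-eigengene means are
#' taken over the other eigengenes, and the overall density is the mean
#' over distinct pairs.
#'
#' @param me_a,me_b Eigengene matrices (modules x samples) over the same
#'   module set; sample sets may differ.
#' @return List: `preservation` (modules x modules), `per_eigengene`
#'   (named means), `density` (scalar in [0, 1]).
#' @export
eigengene_preservation <- function(me_a, me_b) {
  me_a <- if (is.list(me_a)) me_a$values else me_a
  me_b <- if (is.list(me_b)) me_b$values else me_b
  if (!identical(rownames(me_a), rownames(me_b)))
    stop("the two eigengene matrices must cover the same modules")
  a1 <- (1 + stats::cor(t(me_a))) / 2
  a2 <- (1 + stats::cor(t(me_b))) / 2
  pres <- 1 - abs(a1 - a2)
  diag(pres) <- 1
  n <- nrow(pres)
  per <- if (n > 1) (rowSums(pres) - 1) / (n - 1) else stats::setNames(1, rownames(pres))
  density <- if (n > 1) mean(pres[upper.tri(pres)]) else 1
  list(preservation = pres, per_eigengene = per, density = density)
}

#' Module overlap contingency table with Fisher p-values
#'
#' Cross-tabulates two partitions of the same gene universe and attaches a
#' one-sided Fisher exact p-value (hypergeometric upper tail) per cell for
#' overlap enrichment.
#'
#' @param labels_a,labels_b Named integer label vectors over the same
#'   genes.
#' @return List: `counts` (table), `p` (matrix of the same shape).
#' @export
overlap_table <- function(labels_a, labels_b) {
  if (!setequal(names(labels_a), names(labels_b)))
    stop("partitions cover different gene universes")
  labels_b <- labels_b[names(labels_a)]
  counts <- table(a = labels_a, b = labels_b)
  n_univ <- length(labels_a)
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  p <- counts
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    k <- counts[i, j]
    p[i, j] <- stats::phyper(k - 1, row_tot[i], n_univ - row_tot[i],
                             col_tot[j], lower.tail = FALSE)
  }
  list(counts = counts, p = as.matrix(p))
}

#' Two-set consensus module analysis
#'
#' Builds per-set unsigned TOMs at a common power, quantile-scales the
#' second onto the first (optional), takes the elementwise minimum,
#' detects consensus modules on the consensus dissimilarity, merges
#' modules whose eigengenes are close in *both* sets (componentwise
#' minimum of the per-set eigengene correlations, mirroring the TOM
#' rule), and assembles per-set and consensus module-trait tables plus
#' the eigengene preservation report.
#'
#' @param dataset_a,dataset_b Two [coexpr_dataset()]s; their gene
#'   universes are intersected.
#' @param power Soft-thresholding power (default 6).
#' @param min_module_size Minimum module size (default 40).
#' @param merge_cut_height Eigengene merge height (default 0.25).
#' @param scale_toms Quantile-scale the second TOM first (default TRUE).
#' @param gap_fold Passed to [cut_tree_dynamic()].
#' @param max_genes Single-block gene cap.
#' @return A `consensus_report` list: `labels`, `colors`, `eigengenes_a`,
#'   `eigengenes_b`, `trait_a`, `trait_b`, `consensus_trait`,
#'   `preservation`, `n_genes`.
#' @export
run_consensus <- function(dataset_a, dataset_b, power = 6,
                          min_module_size = 40, merge_cut_height = 0.25,
                          scale_toms = TRUE, gap_fold = 4,
                          max_genes = 6000) {
  common <- intersect(rownames(dataset_a$values), rownames(dataset_b$values))
  if (length(common) < min_module_size)
    stop("gene intersection (", length(common), ") below min_module_size")
  a_m <- dataset_a$values[common, , drop = FALSE]
  b_m <- dataset_b$values[common, , drop = FALSE]

  tom_a <- tom_similarity(adjacency_matrix(pearson_correlation(a_m, max_genes), power))
  tom_b <- tom_similarity(adjacency_matrix(pearson_correlation(b_m, max_genes), power))
  if (scale_toms) tom_b <- scale_second_tom(tom_a, tom_b)
  cons <- consensus_tom(tom_a, tom_b)

  dend <- average_linkage(1 - cons)
  labels <- cut_tree_dynamic(dend, min_module_size = min_module_size,
                             gap_fold = gap_fold)
  names(labels) <- common
  labels <- merge_consensus_modules(a_m, b_m, labels, merge_cut_height)

  me_a <- module_eigengenes(a_m, labels)
  me_b <- module_eigengenes(b_m, labels)
  tr_a <- module_trait_relations(me_a, trait_vector(dataset_a))
  tr_b <- module_trait_relations(me_b, trait_vector(dataset_b))
  cons_tr <- cbind(module = tr_a$module,
                   consensus_trait_relation(tr_a$r_case, tr_a$p_case,
                                            tr_b$r_case, tr_b$p_case))
  pres <- eigengene_preservation(me_a, me_b)

  structure(list(labels = labels, colors = module_colors(labels),
                 eigengenes_a = me_a, eigengenes_b = me_b,
                 trait_a = tr_a, trait_b = tr_b,
                 consensus_trait = cons_tr, preservation = pres,
                 n_genes = length(common)),
            class = "consensus_report")
}

# iterative merge on the componentwise minimum of per-set ME correlations
merge_consensus_modules <- function(a_m, b_m, labels, cut_height) {
  labels <- relabel_by_size(labels)
  max_iter <- max(c(labels, 1L)) + 1L
  for (iter in seq_len(max_iter)) {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    cor_a <- stats::cor(t(module_eigengenes(a_m, labels)$values))
    cor_b <- stats::cor(t(module_eigengenes(b_m, labels)$values))
    d <- 1 - pmin(cor_a, cor_b)
    diag(d) <- 0
    grp <- stats::cutree(average_linkage(d), h = cut_height)
    if (length(unique(grp)) == length(mods)) break
    map <- stats::setNames(grp, mods)
    labels[labels > 0] <- map[as.character(labels[labels > 0])]
    storage.mode(labels) <- "integer"
    labels <- relabel_by_size(labels)
  }
  labels
}

#' @export
print.consensus_report <- function(x, ...) {
  n_mod <- length(unique(x$labels[x$labels > 0]))
  cat("consensus_report: ", x$n_genes, " genes, ", n_mod, " consensus modules\n",
      sep = "")
  cat("  eigengene-network preservation density: ",
      fmt_num(x$preservation$density), "\n", sep = "")
  cat("  consensus trait table NA cells: ",
      sum(is.na(x$consensus_trait$r)), "/", nrow(x$consensus_trait), "\n",
      sep = "")
  invisible(x)
}
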