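#' Pearson correlation with a Student-t p-value
#'
#' The two-sided p-value is computed through the regularized incomplete
#' beta function: with `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and
#' `df = n - 2`, `p = I_{df / (df + t^2)}(df / 2, 1 / 2)`. Perfect
#' correlations report the smallest representable positive double instead
#' of zero.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return List with `r` and `p`.
#' @export
correlation_test <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need two vectors of equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, n))
}

# two-sided p for a Pearson r at sample size n, via pbeta
cor_pvalue <- function(r, n) {
  df <- n - 2
  r2 <- pmin(r^2, 1)
  p <- ifelse(r2 >= 1, 0, stats::pbeta(1 - r2, df / 2, 0.5))
  pmax(p, .Machine$double.xmin)
}

#' Module-trait correlation table
#'
#' Correlates every module eigengene with the binary case trait and with
#' its complement (the control indicator; correlations are exact
#' negations). The module with the largest absolute trait correlation per
#' trait column carries the module-significance (MS) flag and is the
#' module reported as trait-related.
#'
#' @param eigengenes Result of [module_eigengenes()] (or a modules x
#'   samples matrix).
#' @param trait Named 0/1 case indicator aligned to the eigengene samples
#'   by id.
#' @param trait_name,complement_name Column labels.
#' @return Data frame: module, r/p against the trait and its complement,
#'   and logical `ms_trait` / `ms_complement` flags.
#' @export
module_trait_relations <- function(eigengenes, trait, trait_name = "case",
                                   complement_name = "control") {
  me <- if (is.list(eigengenes)) eigengenes$values else eigengenes
  if (!is.null(names(trait))) {
    if (!all(colnames(me) %in% names(trait)))
      stop("samples missing from trait vector: ",
           paste(setdiff(colnames(me), names(trait)), collapse = ", "))
    trait <- trait[colnames(me)]
  } else if (length(trait) != ncol(me)) {
    stop("trait length does not match the sample count")
  }
  n <- ncol(me)
  res <- data.frame(module = rownames(me),
                    r = NA_real_, p = NA_real_,
                    r_complement = NA_real_, p_complement = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(me))) {
    ct <- correlation_test(me[i, ], trait)
    res$r[i] <- ct$r
    res$p[i] <- ct$p
    res$r_complement[i] <- -ct$r
    res$p_complement[i] <- ct$p
  }
  res$ms_trait <- seq_len(nrow(res)) == which.max(abs(res$r))
  res$ms_complement <- seq_len(nrow(res)) == which.max(abs(res$r_complement))
  names(res)[2:5] <- c(paste0("r_", trait_name), paste0("p_", trait_name),
                       paste0("r_", complement_name),
                       paste0("p_", complement_name))
  res
}

#' Per-gene trait and connectivity statistics
#'
#' Gene significance (GS) is the signed correlation between a gene's
#' expression and the trait (its absolute value is the classical
#' definition; the sign is kept so direction is reportable). Module
#' membership (kME) is the correlation of each gene with every module
#' eigengene. Intramodular connectivity (kIN) sums a gene's adjacency to
#' the other members of its own module; kTotal sums over all genes.
#'
#' @param dataset A [coexpr_dataset()] or matrix.
#' @param eigengenes Result of [module_eigengenes()].
#' @param adj Adjacency matrix over the same genes.
#' @param labels Integer module labels.
#' @param trait Named 0/1 case indicator.
#' @return Data frame: gene, module, gs, kme_own, kin, ktotal, plus one
#'   `kME<id>` column per module.
#' @export
gene_stats <- function(dataset, eigengenes, adj, labels, trait) {
  m <- if (inherits(dataset, "coexpr_dataset")) dataset$values else dataset
  me <- eigengenes$values
  if (!identical(rownames(m), rownames(adj)))
    stop("dataset and adjacency gene universes differ")
  if (!is.null(names(trait))) trait <- trait[colnames(m)]
  gs <- as.numeric(stats::cor(t(m), trait))
  kme <- stats::cor(t(m), t(me))           # genes x modules
  colnames(kme) <- sub("^ME", "kME", rownames(me))
  a <- adj
  diag(a) <- 0
  ktotal <- rowSums(a)
  kin <- rep(NA_real_, nrow(m))
  for (mod in unique(labels[labels > 0])) {
    idx <- which(labels == mod)
    kin[idx] <- rowSums(a[idx, idx, drop = FALSE])
  }
  kin[labels == 0] <- 0
  kme_own <- rep(NA_real_, nrow(m))
  pos <- labels > 0
  kme_own[pos] <- kme[cbind(which(pos),
                            match(paste0("kME", labels[pos]), colnames(kme)))]
  out <- data.frame(gene = rownames(m), module = as.integer(labels),
                    gs = gs, kme_own = kme_own, kin = kin, ktotal = ktotal,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(kme))
}

#' Hub genes of a module
#'
#' The module's genes ranked by intramodular connectivity, descending;
#' ties break by gene id ascending. If the module has fewer than `top_n`
#' genes, all members are returned.
#'
#' @param stats Result of [gene_stats()].
#' @param module Integer module id.
#' @param top_n Number of hubs to report (default 30).
#' @return Character vector of gene ids, ordered.
#' @export
hub_genes <- function(stats, module, top_n = 30) {
  sub <- stats[stats$module == module, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown module: ", module)
  sub <- sub[order(-sub$kin, sub$gene), , drop = FALSE]
  utils::head(sub$gene, top_n)
}

#' Module membership vs gene significance within a module
#'
#' Correlates signed kME (against the module's own eigengene) with signed
#' GS across the module's members; a strong correlation indicates that the
#' genes central to the module are also the genes tracking the trait.
#'
#' @param stats Result of [gene_stats()].
#' @param module Integer module id (>= 3 members required).
#' @return List with `r` and `p` (from [correlation_test()]).
#' @export
mm_gs_module_summary <- function(stats, module) {
  sub <- stats[stats$module == module, , drop = FALSE]
  if (nrow(sub) < 3) stop("module ", module, " has fewer than 3 genes")
  correlation_test(sub$kme_own, sub$gs)
}
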