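#' Log2-transform an expression matrix
#'
#' Applies `log2(x + offset)`. In auto mode the transform is skipped when a
#' scale heuristic (matrix maximum < 30) indicates the data are already on
#' the log scale, the usual situation for normalized microarray series.
#'
#' @param dataset A [coexpr_dataset()] or bare numeric matrix.
#' @param offset Pseudo-value added before the log (default 1).
#' @param auto Skip the transform when the data look already logged.
#' @return Object of the same type, transformed (or untouched in auto mode).
#' @export
log2_transform <- function(dataset, offset = 1, auto = TRUE) {
  m <- if (inherits(dataset, "coexpr_dataset")) dataset$values else dataset
  if (auto && max(m) < 30) return(dataset)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative value at row ", rownames(m)[bad[1]], ", column ",
         colnames(m)[bad[2]], "; cannot log2-transform")
  }
  out <- log2(m + offset)
  if (inherits(dataset, "coexpr_dataset")) {
    dataset$values <- out
    dataset
  } else out
}

#' Collapse probes to genes
#'
#' Probes annotated to more than one gene are eliminated. When several
#' remaining probes map to the same gene, the whole row of the probe with
#' the largest mean expression across samples is kept ("MaxMean" row
#' selection, not an elementwise maximum). Unmapped probes are dropped.
#'
#' @param probe_matrix Numeric matrix, probes x samples, probe ids as
#'   rownames.
#' @param mapping Data frame with columns `probe`, `gene`; a probe repeated
#'   with different genes is multi-gene and is removed.
#' @return Numeric matrix, genes x samples. Rownames are gene ids; ties in
#'   mean expression break by probe id ascending.
#' @export
collapse_probes <- function(probe_matrix, mapping) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  if (!all(c("probe", "gene") %in% colnames(mapping)))
    stop("mapping needs columns `probe` and `gene`")
  mapping <- unique(mapping[, c("probe", "gene")])
  multi <- unique(mapping$probe[duplicated(mapping$probe)])
  mapping <- mapping[!(mapping$probe %in% multi), , drop = FALSE]
  mapping <- mapping[mapping$probe %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(mapping) == 0) stop("no probes left after collapse")
  means <- rowMeans(probe_matrix)[mapping$probe]
  ord <- order(mapping$gene, -means, mapping$probe)
  mapping <- mapping[ord, , drop = FALSE]
  keep <- mapping[!duplicated(mapping$gene), , drop = FALSE]
  out <- probe_matrix[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  out[order(rownames(out)), , drop = FALSE]
}

#' Empirical-Bayes batch adjustment
#'
#' Removes additive and multiplicative per-gene batch effects with the
#' parametric empirical-Bayes location/scale model (ComBat), protecting the
#' case/control contrast as a model covariate so the trait signal analysed
#' downstream is not absorbed into the batch estimate. With a single batch
#' the data are returned unchanged.
#'
#' @param dataset A [coexpr_dataset()].
#' @return The dataset with batch-adjusted values.
#' @export
combat_adjust <- function(dataset) {
  stopifnot(inherits(dataset, "coexpr_dataset"))
  tab <- table(dataset$batch)
  if (any(tab < 2))
    stop("batch with < 2 samples: ", paste(names(tab)[tab < 2], collapse = ", "))
  if (length(tab) == 1) return(dataset)
  # protect the case/control contrast unless it is absent or confounded
  # (identical within every batch), in which case there is nothing to protect
  mod <- NULL
  if (length(unique(dataset$group)) == 2 &&
      any(rowSums(table(dataset$batch, dataset$group) > 0) > 1)) {
    mod <- stats::model.matrix(~ factor(dataset$group, c("control", "case")))
  }
  adj <- sva::ComBat(dat = dataset$values, batch = dataset$batch, mod = mod)
  dataset$values <- adj
  dataset
}

#' Keep the most variable genes
#'
#' Retains `ceiling(fraction * n_genes)` genes with the largest sample
#' variance; ties at the cutoff break by gene id ascending.
#'
#' @param dataset A [coexpr_dataset()] or matrix.
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return Same type, restricted to the selected genes (original row order
#'   preserved).
#' @export
variance_filter <- function(dataset, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- if (inherits(dataset, "coexpr_dataset")) dataset$values else dataset
  n_keep <- ceiling(fraction * nrow(m))
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m))
  keep <- sort(ord[seq_len(n_keep)])
  if (inherits(dataset, "coexpr_dataset")) {
    dataset$values <- m[keep, , drop = FALSE]
    dataset
  } else m[keep, , drop = FALSE]
}
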