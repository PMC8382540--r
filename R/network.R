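#' Gene-gene Pearson correlation matrix
#'
#' Correlations are computed across samples. A dense-matrix single-block
#' implementation: gene counts above `max_genes` (the block-size guard,
#' default 6,000) are rejected rather than preclustered.
#'
#' @param dataset A [coexpr_dataset()] or genes x samples matrix.
#' @param max_genes Hard cap on the number of genes.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation <- function(dataset, max_genes = 6000) {
  m <- if (inherits(dataset, "coexpr_dataset")) dataset$values else dataset
  if (nrow(m) > max_genes)
    stop(nrow(m), " genes exceed the single-block cap of ", max_genes)
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "))
  r <- stats::cor(t(m))
  diag(r) <- 1
  r
}

#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |cor_ij|^power`; the diagonal is forced to 1.
#'
#' @param cor_matrix Correlation matrix.
#' @param power Soft-thresholding exponent (>= 1).
#' @return Adjacency matrix with attribute `power`.
#' @export
adjacency_matrix <- function(cor_matrix, power) {
  if (power < 1) stop("power must be >= 1")
  a <- abs(cor_matrix)^power
  diag(a) <- 1
  attr(a, "power") <- as.integer(power)
  a
}

#' Per-gene network connectivity
#'
#' `k_i = sum_{j != i} a_ij`.
#'
#' @param adj Adjacency matrix (unit diagonal).
#' @return Named numeric vector of connectivities.
#' @export
connectivity <- function(adj) rowSums(adj) - diag(adj)

#' Signed scale-free topology fit index
#'
#' Connectivities are binned into `n_bins` equal-width bins; the log10 of
#' the per-bin frequency is regressed on the log10 of the per-bin mean
#' connectivity over non-empty bins, and the regression R^2 is returned
#' with the sign flipped when the slope is positive (a genuinely scale-free
#' degree distribution has a negative slope, hence a positive index).
#'
#' @param adj Adjacency matrix, or a connectivity vector directly.
#' @param n_bins Number of equal-width connectivity bins.
#' @return Signed fit index in [-1, 1].
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  k <- if (is.matrix(adj)) connectivity(adj) else adj
  if (length(unique(k)) < 2)
    stop("all connectivities identical; scale-free fit undefined")
  bins <- cut(k, breaks = n_bins)
  mean_k <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  ok <- !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 2) stop("fewer than 2 usable connectivity bins")
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  unname(-sign(slope) * r2)
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power the unsigned adjacency is formed and its signed
#' scale-free fit index and connectivity summaries recorded. The chosen
#' power is the smallest one whose fit reaches `target_r2`; if none does,
#' the power maximizing the fit.
#'
#' @param dataset A [coexpr_dataset()] or matrix.
#' @param powers Candidate powers (default 1..20).
#' @param target_r2 Fit threshold for selection.
#' @param n_bins Bins passed to [scale_free_fit()].
#' @param max_genes Passed to [pearson_correlation()].
#' @return List with `scan` (data frame: power, fit_r2, mean_k, median_k,
#'   max_k) and `chosen_power`.
#' @export
pick_soft_threshold <- function(dataset, powers = 1:20, target_r2 = 0.85,
                                n_bins = 10, max_genes = 6000) {
  r <- pearson_correlation(dataset, max_genes = max_genes)
  scan <- data.frame(power = powers, fit_r2 = NA_real_, mean_k = NA_real_,
                     median_k = NA_real_, max_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- adjacency_matrix(r, powers[i])
    k <- connectivity(a)
    scan$mean_k[i] <- mean(k)
    scan$median_k[i] <- stats::median(k)
    scan$max_k[i] <- max(k)
    scan$fit_r2[i] <- tryCatch(scale_free_fit(k, n_bins = n_bins),
                               error = function(e) NA_real_)
  }
  hit <- which(!is.na(scan$fit_r2) & scan$fit_r2 >= target_r2)
  chosen <- if (length(hit) > 0) powers[min(hit)] else
    powers[which.max(scan$fit_r2)]
  list(scan = scan, chosen_power = chosen)
}

#' Topological overlap similarity
#'
#' For an unsigned adjacency with unit diagonal,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1.
#'
#' @param adj Adjacency matrix.
#' @return TOM similarity matrix in [0, 1].
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 1
  L <- a %*% a - 2 * a          # removes u = i and u = j terms (diag = 1)
  k <- rowSums(a) - 1
  min_k <- outer(k, k, pmin)
  tom <- (L + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Topological overlap dissimilarity (1 - TOM)
#'
#' @param adj Adjacency matrix.
#' @return Dissimilarity matrix with zero diagonal.
#' @export
tom_dissimilarity <- function(adj) 1 - tom_similarity(adj)
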