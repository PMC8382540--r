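#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated — set name, description,
#' then gene ids. Uses fgsea's reader when available.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in the query list against a
#' gene universe: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with
#' `N` the universe size, `K` the (universe-intersected) set size, `n` the
#' query size and `k` the overlap. Bonferroni correction is applied over
#' the number of sets tested; set genes outside the universe are dropped
#' (with their count recorded).
#'
#' @param query Character vector of gene ids (must lie in the universe).
#' @param collection Named list of gene-id sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the background gene universe.
#' @param alpha Bonferroni significance threshold (default 1e-4).
#' @return Data frame sorted by p ascending (ties by set name): set, k, K,
#'   n, N, dropped_genes, p, p_bonferroni, significant.
#' @export
hypergeometric_ora <- function(query, collection, universe, alpha = 1e-4) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0 || length(universe) == 0)
    stop("query and universe must be non-empty")
  extra <- setdiff(query, universe)
  if (length(extra) > 0)
    stop("query genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(collection), function(nm) {
    full <- unique(collection[[nm]])
    set <- intersect(full, universe)
    k <- length(intersect(query, set))
    K <- length(set)
    p <- stats::phyper(k - 1, K, n_univ - K, n_query, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n_query, N = n_univ,
               dropped_genes = length(full) - K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out[order(out$p, out$set), , drop = FALSE]
}
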