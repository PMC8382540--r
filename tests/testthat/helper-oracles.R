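# Small simulation used by most unit tests (fast; the full study-sized
# configuration is exercised in the acceptance tests).
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(n_background_genes = 300,
                   module_sizes = c(60, 50, 40),
                   trait_effect_sizes = c(1.5, 0, 0),
                   cohort_specs = list(
                     list(n_cases = 10, n_controls = 15, batch = "b1"),
                     list(n_cases = 12, n_controls = 20, batch = "b2")),
                   seed = seed)
  args <- list(...)
  defaults[names(args)] <- args   # plain replacement, no recursive merging
  do.call(sim_config, defaults)
}

# random valid adjacency: symmetric, entries in [0,1], unit diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# TOM oracle: explicit per-pair sums, independent of the matrix-product path
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u <- setdiff(seq_len(n), c(i, j))
    L <- sum(a[i, u] * a[u, j])
    out[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# brute-force UPGMA returning the cophenetic distance matrix
upgma_cophenetic_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  avg_d <- function(ci, cj) mean(d[clusters[[ci]], clusters[[cj]]])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_h <- Inf
    for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
      if (jj <= ii) next
      h <- avg_d(idx[ii], idx[jj])
      if (h < best_h) { best_h <- h; best <- c(idx[ii], idx[jj]) }
    }
    mi <- clusters[[best[1]]]; mj <- clusters[[best[2]]]
    coph[mi, mj] <- best_h; coph[mj, mi] <- best_h
    clusters[[best[1]]] <- c(mi, mj)
    active[best[2]] <- FALSE
  }
  coph
}

# hypergeometric upper tail by explicit enumeration with choose()
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  if (k <= max(0, n - (N - K))) return(1)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# two-sided correlation p-value by numeric quadrature of the t density
cor_p_quadrature <- function(r, n) {
  df <- n - 2
  t <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  2 * stats::integrate(function(x) stats::dt(x, df), t, Inf,
                       rel.tol = 1e-12)$value
}
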