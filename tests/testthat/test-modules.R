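test_that("average linkage reproduces hand-worked UPGMA merges", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tree <- average_linkage(d)
  expect_equal(tree$height, c(0.1, 0.9))
  expect_equal(sort(abs(tree$merge[1, ])), c(1, 2))
  # identical rows merge first at height 0
  d0 <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3, 3)
  expect_equal(average_linkage(d0)$height[1], 0)
  asym <- d; asym[1, 2] <- 0.4
  expect_error(average_linkage(asym), "symmetric")
})

test_that("average linkage agrees with a brute-force UPGMA oracle", {
  set.seed(10)
  for (trial in 1:25) {
    n <- sample(6:15, 1)
    d <- as.matrix(stats::dist(matrix(rnorm(n * 3), n, 3)))
    tree <- average_linkage(d)
    expect_equal(unname(as.matrix(stats::cophenetic(tree))),
                 upgma_cophenetic_oracle(d), tolerance = 1e-10)
  }
})

test_that("the root split separates two planted dissimilarity blocks", {
  set.seed(11)
  n <- 20
  d <- matrix(runif(n * n, 0.8, 0.9), n, n)
  block <- rep(1:2, each = n / 2)
  within <- outer(block, block, "==")
  d[within] <- runif(sum(within), 0.1, 0.2)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tree <- average_linkage(d)
  top_split <- stats::cutree(tree, k = 2)
  expect_equal(length(unique(paste(block, top_split))), 2)
})

test_that("the dynamic cut recovers planted modules and drops small branches", {
  # no batch structure (the cut, not ComBat, is under test); loadings high
  # enough that module-periphery overlap is separable from background at
  # this sample size
  sim <- simulate_pair(small_sim_config(
    batch_shift_sd = 0, loading_range = c(0.75, 0.95),
    cohort_specs = list(list(n_cases = 30, n_controls = 30, batch = "b1"),
                        list(n_cases = 30, n_controls = 30, batch = "b2"))))
  ds <- variance_filter(merge_cohorts(sim), 0.5)
  adj <- adjacency_matrix(pearson_correlation(ds), 6)
  labels <- cut_tree_dynamic(average_linkage(tom_dissimilarity(adj)),
                             min_module_size = 30)
  truth <- sim$truth$partition[rownames(ds$values)]
  merged <- merge_close_modules(ds, labels)$labels
  expect_equal(length(unique(merged[merged > 0])), 3)
  # module recovery: restricted to planted-module genes the partitions agree
  in_mod <- truth > 0
  expect_gt(mclust::adjustedRandIndex(merged[in_mod], truth[in_mod]), 0.95)
  # every detected module is dominated by one planted module; background
  # genes that correlate with a latent factor by chance at finite n attach
  # legitimately, but never form the bulk of a module
  for (mod in unique(merged[merged > 0])) {
    members <- truth[merged == mod]
    expect_gt(max(table(members[members > 0])) / length(members), 0.6)
  }
  expect_gt(mean(merged[truth == 0] == 0), 0.25)
  # a 20-gene module cannot reach min_module_size 40
  sim2 <- simulate_pair(sim_config(
    n_background_genes = 0, module_sizes = c(60, 20),
    trait_effect_sizes = 0, loading_range = c(0.7, 0.95),
    cohort_specs = list(list(n_cases = 30, n_controls = 30, batch = "b1")),
    batch_shift_sd = 0, seed = 2))
  ds2 <- sim2$set1
  adj2 <- adjacency_matrix(pearson_correlation(ds2), 6)
  lab2 <- cut_tree_dynamic(average_linkage(tom_dissimilarity(adj2)),
                           min_module_size = 40)
  truth2 <- sim2$truth$partition
  expect_true(all(lab2[truth2 == 2] == 0))
  expect_gt(mean(lab2[truth2 == 1] > 0), 0.9)
})

test_that("a single tight cluster yields exactly one module", {
  sim <- simulate_pair(sim_config(
    n_background_genes = 0, module_sizes = 60, trait_effect_sizes = 0,
    loading_range = c(0.9, 0.95), noise_sd = 0.3, batch_shift_sd = 0,
    cohort_specs = list(list(n_cases = 15, n_controls = 15, batch = "b1")),
    seed = 3))
  adj <- adjacency_matrix(pearson_correlation(sim$set1), 6)
  labels <- cut_tree_dynamic(average_linkage(tom_dissimilarity(adj)),
                             min_module_size = 40)
  expect_equal(length(setdiff(unique(labels), 0L)), 1)
  expect_gte(mean(labels == 1L), 0.95)
})

test_that("eigengenes summarize modules as first principal components", {
  # identical genes: eigengene is the shared z-profile, variance fully explained
  prof <- rnorm(20)
  m <- matrix(rep(prof, 5), 5, 20, byrow = TRUE) + 0
  m <- m * c(1, 2, 3, 4, 5)  # same shape, different scale
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:20))
  me <- module_eigengenes(m, rep(1L, 5))
  z <- scale(prof)[, 1]
  expect_equal(abs(cor(me$values[1, ], z)), 1, tolerance = 1e-10)
  expect_gt(cor(me$values[1, ], colMeans(t(scale(t(m))))), 0)
  expect_equal(unname(me$var_explained[1]), 1, tolerance = 1e-10)
  expect_equal(sum(me$values[1, ]^2), 1)  # unit norm

  # two orthogonal z-profiles split the variance evenly
  x <- rnorm(50)
  y <- rnorm(50)
  y <- residuals(lm(y ~ x))
  m2 <- rbind(g1 = x, g2 = y)
  colnames(m2) <- paste0("s", 1:50)
  me2 <- module_eigengenes(m2, c(1L, 1L))
  expect_equal(unname(me2$var_explained[1]), 0.5, tolerance = 1e-10)

  # noise-free factor model: eigengene recovers the planted latent factor
  sim <- simulate_pair(small_sim_config(noise_sd = 0, batch_shift_sd = 0))
  truth <- sim$truth$partition
  me3 <- module_eigengenes(sim$set1$values, truth)
  u <- sim$truth$latent_factors[1, colnames(sim$set1$values)]
  expect_gt(abs(cor(me3$values["ME1", ], u)), 0.999)
})

test_that("merging collapses correlated eigengenes to a fixed point", {
  set.seed(12)
  # two modules driven by highly correlated factors, one independent
  n_s <- 60
  f1 <- rnorm(n_s)
  f2 <- 0.97 * f1 + sqrt(1 - 0.97^2) * rnorm(n_s)
  f3 <- rnorm(n_s)
  mk <- function(f, n_g, tag) {
    m <- t(sapply(seq_len(n_g), function(i) 0.9 * f + 0.1 * rnorm(n_s)))
    rownames(m) <- paste0(tag, seq_len(n_g))
    m
  }
  m <- rbind(mk(f1, 50, "a"), mk(f2, 45, "b"), mk(f3, 40, "c"))
  colnames(m) <- paste0("s", seq_len(n_s))
  labels <- rep(1:3, c(50, 45, 40))
  me <- module_eigengenes(m, labels)
  expect_gt(cor(me$values[1, ], me$values[2, ]), 0.75)
  merged <- merge_close_modules(m, labels, cut_height = 0.25)
  expect_equal(length(unique(merged$labels)), 2)
  # modules a and b fused, c untouched
  expect_equal(length(unique(merged$labels[1:95])), 1)
  expect_equal(length(unique(merged$labels[96:135])), 1)
  # fixed point: no remaining pair above 1 - cut_height
  final_cor <- cor(t(merged$eigengenes$values))
  expect_true(all(final_cor[upper.tri(final_cor)] <= 0.75 + 1e-12))

  # weakly correlated modules stay apart
  m2 <- rbind(mk(f1, 50, "a"), mk(f3, 40, "c"))
  colnames(m2) <- paste0("s", seq_len(n_s))
  merged2 <- merge_close_modules(m2, rep(1:2, c(50, 40)))
  expect_equal(length(unique(merged2$labels)), 2)
})

test_that("labels are ranked by size with stable color names", {
  labels <- c(rep(3L, 5), rep(1L, 10), rep(2L, 7), 0L)
  ranked <- relabel_by_size(labels)
  expect_equal(unname(table(ranked[ranked > 0])[c("1", "2", "3")]),
               c(10L, 7L, 5L), ignore_attr = TRUE)
  expect_equal(ranked[length(ranked)], 0L)
  cols <- module_colors(ranked)
  expect_equal(unname(cols[6]), "turquoise")   # largest module
  expect_equal(unname(cols[16]), "blue")       # second largest
  expect_equal(unname(cols[1]), "brown")
  expect_equal(unname(cols[length(cols)]), "grey")
})
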