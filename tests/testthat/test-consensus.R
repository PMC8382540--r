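test_that("quantile scaling matches TOM distributions and preserves order", {
  set.seed(20)
  t1 <- tom_similarity(random_adjacency(15))
  expect_equal(scale_second_tom(t1, t1), t1)  # exponent 1
  t2 <- tom_similarity(random_adjacency(15))
  t2s <- scale_second_tom(t1, t2)
  off <- upper.tri(t1)
  # the exact q95 value maps onto t1's; the sample quantile interpolates
  # between order statistics, hence the loose tolerance
  expect_equal(unname(quantile(t2s[off], 0.95)),
               unname(quantile(t1[off], 0.95)), tolerance = 1e-3)
  e <- log(quantile(t1[off], 0.95)) / log(quantile(t2[off], 0.95))
  expect_equal(unname(t2s[1, 2]), unname(t2[1, 2]^e), tolerance = 1e-12)
  expect_equal(order(t2s[off]), order(t2[off]))  # monotone power map
  # q_a = 0.25, q_b = 0.5 -> exponent log(.25)/log(.5) = 2
  expect_equal(log(0.25) / log(0.5), 2)
  m_a <- matrix(0.25, 4, 4); diag(m_a) <- 1
  m_b <- matrix(0.5, 4, 4); diag(m_b) <- 1
  expect_equal(scale_second_tom(m_a, m_b)[1, 2], 0.25)
})

test_that("consensus TOM is the elementwise minimum", {
  set.seed(21)
  for (trial in 1:100) {
    a <- tom_similarity(random_adjacency(20))
    b <- tom_similarity(random_adjacency(20))
    cons <- consensus_tom(a, b)
    expect_true(all(cons <= a + 1e-15) && all(cons <= b + 1e-15))
    expect_true(all(cons >= 0 & cons <= 1))
    expect_true(all(cons == pmin(a, b)))
  }
  t1 <- tom_similarity(random_adjacency(10))
  expect_identical(consensus_tom(t1, t1), t1)
  t2 <- t1
  rownames(t2)[1] <- "other"
  expect_error(consensus_tom(t1, t2), "misaligned")
})

test_that("the consensus trait rule keeps the weaker same-sign correlation", {
  expect_equal(consensus_trait_relation(0.5, 0.01, 0.8, 0.02)$r, 0.5)
  expect_equal(consensus_trait_relation(-0.4, 0.03, -0.6, 0.01)$r, -0.4)
  expect_true(is.na(consensus_trait_relation(0.5, 0.01, -0.3, 0.2)$r))
  expect_true(is.na(consensus_trait_relation(0, 1, 0.4, 0.01)$r))
  # the reported p is the larger (weaker) of the two
  expect_equal(consensus_trait_relation(0.5, 0.01, 0.8, 0.02)$p, 0.02)
  # symmetric in its arguments, sign-equivariant
  set.seed(22)
  r1 <- runif(50, -1, 1); r2 <- runif(50, -1, 1)
  p1 <- runif(50); p2 <- runif(50)
  fwd <- consensus_trait_relation(r1, p1, r2, p2)
  expect_equal(consensus_trait_relation(r2, p2, r1, p1), fwd)
  neg <- consensus_trait_relation(-r1, p1, -r2, p2)
  expect_equal(neg$r, -fwd$r)
})

test_that("eigengene preservation matches hand-worked adjacency differences", {
  set.seed(23)
  me <- matrix(rnorm(4 * 30), 4, 30,
               dimnames = list(paste0("ME", 1:4), paste0("s", 1:30)))
  ident <- eigengene_preservation(me, me)
  expect_true(all(ident$preservation == 1))
  expect_equal(ident$density, 1)
  # cor +1 in one set, -1 in the other: preservation 0
  f <- rnorm(30)
  me_a <- rbind(ME1 = f, ME2 = f + 1e-14)
  me_b <- rbind(ME1 = f, ME2 = -f)
  colnames(me_a) <- colnames(me_b) <- paste0("s", 1:30)
  pr <- eigengene_preservation(me_a, me_b)
  expect_equal(pr$preservation[1, 2], 0, tolerance = 1e-10)
  # cor 0.5 vs 0.1: 1 - |0.75 - 0.55| = 0.8
  mk_pair <- function(rho) {
    a <- rnorm(5000)
    rbind(ME1 = a, ME2 = rho * a + sqrt(1 - rho^2) * rnorm(5000))
  }
  # construct exact correlations instead: two vectors with cor exactly rho
  exact_pair <- function(rho) {
    theta <- acos(rho)
    s <- seq_len(8)
    x <- scale(rnorm(8))[, 1]
    y0 <- scale(residuals(lm(rnorm(8) ~ x)))[, 1]
    y <- cos(theta) * x + sin(theta) * y0
    m <- rbind(ME1 = x, ME2 = y)
    colnames(m) <- paste0("s", s)
    m
  }
  set.seed(24)
  pa <- exact_pair(0.5)
  pb <- exact_pair(0.1)
  pr2 <- eigengene_preservation(pa, pb)
  expect_equal(pr2$preservation[1, 2], 0.8, tolerance = 1e-10)
  expect_equal(pr2$density, 0.8, tolerance = 1e-10)
  # density invariant to module reordering and bounded
  me_c <- matrix(rnorm(4 * 30), 4, 30,
                 dimnames = dimnames(me))
  d1 <- eigengene_preservation(me, me_c)$density
  perm <- c(3, 1, 4, 2)
  d2 <- eigengene_preservation(me[perm, ], me_c[perm, ])$density
  expect_equal(d1, d2)
  expect_true(d1 >= 0 && d1 <= 1)
})

test_that("overlap tables count intersections with exact Fisher tails", {
  labels <- setNames(rep(1:3, c(10, 8, 6)), sprintf("g%02d", 1:24))
  ident <- overlap_table(labels, labels)
  expect_equal(unname(diag(ident$counts)), c(10, 8, 6))
  expect_equal(sum(ident$counts) - sum(diag(ident$counts)), 0)
  expect_equal(unname(rowSums(ident$counts)), c(10, 8, 6))
  # universe 20, two size-5 modules overlapping completely: p = 1/C(20,5)
  la <- setNames(c(rep(1, 5), rep(2, 15)), sprintf("g%02d", 1:20))
  lb <- setNames(c(rep(7, 5), rep(8, 15)), sprintf("g%02d", 1:20))
  ov <- overlap_table(la, lb)
  expect_equal(ov$counts["1", "7"], 5, ignore_attr = TRUE)
  expect_equal(ov$p["1", "7"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(ov$p["1", "7"], hyper_tail_oracle(5, 5, 5, 20))
  expect_error(overlap_table(la, lb[1:10]), "universe")
})

test_that("overlap p-values are near-uniform for independent partitions", {
  set.seed(25)
  n_genes <- 100000
  genes <- sprintf("g%06d", seq_len(n_genes))
  la <- setNames(sample(1:32, n_genes, replace = TRUE), genes)
  lb <- setNames(sample(1:32, n_genes, replace = TRUE), genes)
  ov <- overlap_table(la, lb)
  ks <- suppressWarnings(ks.test(as.numeric(ov$p), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("consensus of a dataset with itself reproduces the single-set run", {
  sim <- simulate_pair(small_sim_config())
  ds <- sim$set1
  rep1 <- run_consensus(ds, ds, power = 6, min_module_size = 30)
  adj <- adjacency_matrix(pearson_correlation(ds), 6)
  single0 <- cut_tree_dynamic(average_linkage(tom_dissimilarity(adj)),
                              min_module_size = 30)
  single <- merge_close_modules(ds, single0)$labels
  expect_gt(mclust::adjustedRandIndex(rep1$labels, single), 0.999)
  expect_equal(rep1$preservation$density, 1)
  expect_equal(rep1$trait_a, rep1$trait_b)
})

test_that("a module planted in only one set is absent from the consensus", {
  base <- small_sim_config(
    seed = 31, batch_shift_sd = 0, loading_range = c(0.75, 0.95),
    cohort_specs = list(list(n_cases = 30, n_controls = 30, batch = "b1"),
                        list(n_cases = 30, n_controls = 30, batch = "b2")))
  sim <- simulate_pair(base)
  a <- sim$set1
  b <- sim$set2
  # destroy module 2 in set b: replace its genes with pure noise
  idx <- names(which(sim$truth$partition == 2))
  set.seed(32)
  b$values[idx, ] <- 8 + matrix(rnorm(length(idx) * ncol(b$values)),
                                length(idx), ncol(b$values))
  rep2 <- run_consensus(a, b, power = 6, min_module_size = 30,
                        scale_toms = FALSE)
  truth <- sim$truth$partition[names(rep2$labels)]
  # genes of the destroyed module end up unassigned; intact modules survive
  expect_gt(mean(rep2$labels[truth == 2] == 0), 0.9)
  expect_gt(mean(rep2$labels[truth == 1] > 0), 0.9)
  expect_gt(mean(rep2$labels[truth == 3] > 0), 0.9)
  # at the network level the destroyed pairs collapse toward the background
  # floor regardless of quantile scaling, far below intact-module overlap
  tom_a <- tom_similarity(adjacency_matrix(pearson_correlation(a$values), 6))
  tom_b <- tom_similarity(adjacency_matrix(pearson_correlation(b$values), 6))
  ct <- consensus_tom(tom_a, scale_second_tom(tom_a, tom_b))
  med <- function(ii) {
    m <- ct[ii, ii]
    median(m[upper.tri(m)])
  }
  i1 <- which(sim$truth$partition == 1)
  i2 <- match(idx, rownames(ct))
  expect_lt(med(i2), 0.01 * med(i1))
})
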