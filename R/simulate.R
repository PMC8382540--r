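#' Configuration for the two-cohort coexpression simulator
#'
#' Defines a latent-factor model for planted coexpression modules across two
#' case/control cohorts. Gene `g` in module `m` has expression
#' `x_gs = lambda_g * u_m(s) + eps_gs`, where `u_m` is a standardized latent
#' factor (standard normal, shifted in cases by the module's trait effect in
#' latent-SD units before standardization), `lambda_g` is drawn uniformly
#' from the loading range and `eps_gs ~ N(0, noise_sd^2)`. Background genes
#' are pure noise. Every gene additionally receives a per-cohort additive
#' batch shift `gamma_gb ~ N(0, batch_shift_sd^2)` shared by all samples of
#' the cohort, and optionally a per-cohort multiplicative scale factor.
#'
#' The defaults mirror the study design the package targets: two microarray
#' cohorts of 17 case / 30 control and 21 case / 59 control blood samples,
#' five planted modules (300/200/150/100/60 genes), a trait effect of 1.5
#' latent SD on the largest module, 2,000 background genes, unit noise and a
#' batch SD of 1 on the log2 scale.
#'
#' @param n_background_genes Number of pure-noise genes.
#' @param module_sizes Integer vector of planted module sizes (all >= 1).
#' @param loading_range Length-2 numeric in (0, 1]: min/max factor loading.
#' @param trait_effect_sizes Per-module latent mean shift (case vs control)
#'   in latent-SD units; recycled/padded with zeros to the module count.
#' @param cohort_specs List of `list(n_cases=, n_controls=, batch=)`; each
#'   cohort needs >= 2 samples per group.
#' @param batch_shift_sd SD of the per-gene additive cohort shift (log2 units).
#' @param batch_scale_sd SD of log2 per-gene multiplicative cohort scale
#'   factors; 0 (default) disables multiplicative batch effects.
#' @param module_factor_cor Correlation between the latent factors of
#'   consecutive module pairs; 0 (default) gives independent modules. Used to
#'   exercise eigengene-based module merging.
#' @param noise_sd Residual SD.
#' @param baseline Additive constant giving values a realistic log2 location.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_background_genes = 2000,
                       module_sizes = c(300, 200, 150, 100, 60),
                       loading_range = c(0.6, 0.95),
                       trait_effect_sizes = c(1.5, 0, 0, 0, 0),
                       cohort_specs = list(
                         list(n_cases = 17, n_controls = 30, batch = "b1"),
                         list(n_cases = 21, n_controls = 59, batch = "b2")),
                       batch_shift_sd = 1,
                       batch_scale_sd = 0,
                       module_factor_cor = 0,
                       noise_sd = 1,
                       baseline = 8,
                       seed = 1) {
  if (any(module_sizes < 1)) stop("all module sizes must be >= 1")
  if (length(loading_range) != 2 || any(loading_range <= 0) ||
      any(loading_range > 1) || loading_range[1] > loading_range[2])
    stop("loading_range must be an increasing pair within (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(module_factor_cor) >= 1) stop("module_factor_cor must be in (-1, 1)")
  for (cs in cohort_specs) {
    if (cs$n_cases < 2 || cs$n_controls < 2)
      stop("each cohort needs >= 2 samples per group (degenerate cohort)")
  }
  eff <- rep_len(c(trait_effect_sizes, rep(0, length(module_sizes))),
                 length(module_sizes))
  structure(list(n_background_genes = n_background_genes,
                 module_sizes = as.integer(module_sizes),
                 loading_range = loading_range,
                 trait_effect_sizes = eff,
                 cohort_specs = cohort_specs,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_sd = batch_scale_sd,
                 module_factor_cor = module_factor_cor,
                 noise_sd = noise_sd,
                 baseline = baseline,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pair of case/control cohorts with planted modules
#'
#' Draws the gene-level parameters (loadings, module assignment) once for a
#' shared gene universe, then generates each cohort with its own samples,
#' noise and batch effects. The planted partition, latent factors and trait
#' vector are returned as ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements `set1`, `set2` (each a [coexpr_dataset()])
#'   and `truth`: a list holding `partition` (named integer vector, 0 =
#'   background), `latent_factors` (modules x all samples), `trait`
#'   (0/1 across all samples, set1 first) and `loadings`.
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_mod <- length(config$module_sizes)
  n_genes <- sum(config$module_sizes) + config$n_background_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  partition <- rep.int(c(seq_len(n_mod), 0L),
                       c(config$module_sizes, config$n_background_genes))
  names(partition) <- gene_ids
  loadings <- stats::runif(n_genes, config$loading_range[1],
                           config$loading_range[2])
  loadings[partition == 0L] <- 0
  names(loadings) <- gene_ids

  sets <- vector("list", length(config$cohort_specs))
  factors <- list()
  trait_all <- numeric(0)
  sample_offset <- 0L
  for (ci in seq_along(config$cohort_specs)) {
    cs <- config$cohort_specs[[ci]]
    n_s <- cs$n_cases + cs$n_controls
    sample_ids <- sprintf("%s_s%03d", cs$batch, seq_len(n_s))
    group <- c(rep("case", cs$n_cases), rep("control", cs$n_controls))
    case_ind <- as.numeric(group == "case")

    # latent factors: standard normal + trait shift, then standardized;
    # optional correlation between consecutive modules via a shared component
    u <- matrix(stats::rnorm(n_mod * n_s), n_mod, n_s)
    if (config$module_factor_cor != 0 && n_mod >= 2) {
      rho <- config$module_factor_cor
      for (m in seq(2, n_mod, by = 2)) {
        u[m, ] <- rho * u[m - 1, ] + sqrt(1 - rho^2) * u[m, ]
      }
    }
    u <- u + config$trait_effect_sizes %o% case_ind
    u <- t(scale(t(u)))  # mean 0, sd 1 per module across the cohort

    eps <- matrix(stats::rnorm(n_genes * n_s, sd = config$noise_sd), n_genes, n_s)
    lam_u <- matrix(0, n_genes, n_s)
    in_mod <- partition != 0L
    lam_u[in_mod, ] <- loadings[in_mod] * u[partition[in_mod], , drop = FALSE]
    x <- lam_u + eps

    gamma <- stats::rnorm(n_genes, sd = config$batch_shift_sd)
    if (config$batch_scale_sd > 0) {
      scale_fac <- 2^stats::rnorm(n_genes, sd = config$batch_scale_sd)
      x <- x * scale_fac
    }
    x <- x + gamma + config$baseline
    dimnames(x) <- list(gene_ids, sample_ids)

    sets[[ci]] <- coexpr_dataset(x, group = group,
                                 batch = rep(cs$batch, n_s))
    colnames(u) <- sample_ids
    factors[[ci]] <- u
    trait_all <- c(trait_all, stats::setNames(case_ind, sample_ids))
    sample_offset <- sample_offset + n_s
  }

  latent <- do.call(cbind, factors)
  rownames(latent) <- paste0("M", seq_len(n_mod))
  list(set1 = sets[[1]], set2 = if (length(sets) > 1) sets[[2]] else NULL,
       truth = list(partition = partition, latent_factors = latent,
                    trait = trait_all, loadings = loadings))
}

#' Merge the two simulated cohorts into one dataset
#'
#' Column-binds the cohorts; batch labels are retained so batch adjustment
#' can be exercised downstream.
#'
#' @param sim Result of [simulate_pair()].
#' @return A [coexpr_dataset()] over all samples.
#' @export
merge_cohorts <- function(sim) {
  stopifnot(!is.null(sim$set2))
  if (!identical(rownames(sim$set1$values), rownames(sim$set2$values)))
    stop("cohorts must share the gene universe")
  coexpr_dataset(cbind(sim$set1$values, sim$set2$values),
                 group = c(sim$set1$group, sim$set2$group),
                 batch = c(sim$set1$batch, sim$set2$batch))
}

#' Write a simulation to TSV files
#'
#' Emits per-cohort expression + annotation tables and the ground-truth
#' partition (gene id, module label).
#'
#' @param sim Result of [simulate_pair()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$set1, file.path(dir, "set1_expression.tsv"),
                   file.path(dir, "set1_samples.tsv"))
  if (!is.null(sim$set2))
    write_expression(sim$set2, file.path(dir, "set2_expression.tsv"),
                     file.path(dir, "set2_samples.tsv"))
  gt <- data.frame(gene = names(sim$truth$partition),
                   module = as.integer(sim$truth$partition))
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
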