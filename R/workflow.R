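write_df_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merged-dataset coexpression workflow
#'
#' Runs the full single-network chain on one (typically batch-merged)
#' dataset: optional log2 transform (auto-skipped for logged data),
#' optional probe collapse, empirical-Bayes batch adjustment (skipped with
#' one batch), top-variance filtering, soft-threshold selection (or a
#' fixed power), unsigned TOM, average-linkage clustering, adaptive tree
#' cut, eigengene-based module merging, module-trait relations, per-gene
#' statistics and hub lists. All stage tables and a JSON manifest
#' (parameters, seed, per-stage row counts) are written to `out_dir`.
#'
#' @param dataset A [coexpr_dataset()] (probe- or gene-level).
#' @param out_dir Output directory.
#' @param probe_mapping Optional probe-to-gene data frame for
#'   [collapse_probes()].
#' @param variance_fraction Fraction of genes kept (default 0.25).
#' @param power Fixed soft-thresholding power; `NULL` (default) scans
#'   powers 1..20 and picks the smallest reaching `target_r2`.
#' @param target_r2 Scale-free fit threshold for the scan.
#' @param min_module_size,merge_cut_height,gap_fold,max_genes
#'   Module-detection parameters (defaults 40, 0.25, 0.25, 6000).
#' @param top_n_hubs Hub genes reported per module (default 30).
#' @param seed Recorded in the manifest; the chain itself is
#'   deterministic.
#' @return Invisibly, a list with the filtered dataset, scan, adjacency,
#'   TOM, dendrogram, labels, colors, eigengenes, trait table, gene stats
#'   and hub lists.
#' @export
run_merged <- function(dataset, out_dir, probe_mapping = NULL,
                       variance_fraction = 0.25, power = NULL,
                       target_r2 = 0.85, min_module_size = 40,
                       merge_cut_height = 0.25, gap_fold = 4,
                       max_genes = 6000, top_n_hubs = 30, seed = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = list(
    variance_fraction = variance_fraction, power = power,
    target_r2 = target_r2, min_module_size = min_module_size,
    merge_cut_height = merge_cut_height, gap_fold = gap_fold,
    max_genes = max_genes, top_n_hubs = top_n_hubs),
    seed = seed, stages = list())
  stage <- function(name, n) manifest$stages[[name]] <<- n

  dataset <- log2_transform(dataset)
  stage("input_genes", nrow(dataset$values))
  stage("n_samples", ncol(dataset$values))
  if (!is.null(probe_mapping)) {
    collapsed <- collapse_probes(dataset$values, probe_mapping)
    dataset <- coexpr_dataset(collapsed, dataset$group, dataset$batch)
    stage("collapsed_genes", nrow(dataset$values))
  }
  dataset <- combat_adjust(dataset)
  dataset <- variance_filter(dataset, variance_fraction)
  stage("filtered_genes", nrow(dataset$values))
  write_expression(dataset, file.path(out_dir, "expression_filtered.tsv"),
                   file.path(out_dir, "samples.tsv"))

  scan <- NULL
  if (is.null(power)) {
    st <- pick_soft_threshold(dataset, target_r2 = target_r2,
                              max_genes = max_genes)
    scan <- st$scan
    power <- st$chosen_power
    write_df_tsv(scan, file.path(out_dir, "soft_threshold_scan.tsv"))
  }
  stage("power", power)

  adj <- adjacency_matrix(pearson_correlation(dataset, max_genes), power)
  tom <- tom_similarity(adj)
  dend <- average_linkage(1 - tom)
  labels0 <- cut_tree_dynamic(dend, min_module_size = min_module_size,
                              gap_fold = gap_fold)
  stage("modules_premerge", length(unique(labels0[labels0 > 0])))
  merged <- merge_close_modules(dataset, labels0, merge_cut_height)
  labels <- merged$labels
  me <- merged$eigengenes
  stage("modules", length(unique(labels[labels > 0])))
  stage("unassigned_genes", sum(labels == 0))

  part <- data.frame(gene = rownames(dataset$values),
                     module = as.integer(labels),
                     color = module_colors(labels))
  write_df_tsv(part, file.path(out_dir, "module_partition.tsv"))
  write_matrix_tsv(me$values, file.path(out_dir, "eigengenes.tsv"),
                   id_col = "module")

  trait <- trait_vector(dataset)
  mt <- module_trait_relations(me, trait)
  write_df_tsv(mt, file.path(out_dir, "module_trait.tsv"))
  gs <- gene_stats(dataset, me, adj, labels, trait)
  write_df_tsv(gs, file.path(out_dir, "gene_stats.tsv"))

  hubs <- lapply(sort(unique(labels[labels > 0])), function(mod)
    data.frame(module = mod, rank = NA, gene = hub_genes(gs, mod, top_n_hubs)))
  hubs <- do.call(rbind, lapply(hubs, function(h) {
    h$rank <- seq_len(nrow(h)); h
  }))
  write_df_tsv(hubs, file.path(out_dir, "hub_genes.tsv"))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dataset = dataset, scan = scan, power = power, adj = adj,
                 tom = tom, dendrogram = dend, labels = labels,
                 colors = module_colors(labels), eigengenes = me,
                 module_trait = mt, gene_stats = gs, hubs = hubs,
                 manifest = manifest))
}

#' Two-set consensus workflow
#'
#' Preprocesses both cohorts on their shared gene universe (per-set
#' log2/auto, variance filter on the mean of per-set variances so both
#' sets retain the same genes), runs [run_consensus()], and writes the
#' consensus partition, per-set and consensus trait tables, preservation
#' report and a JSON summary. When a merged-run partition is supplied the
#' consensus-versus-merged overlap table is written as well.
#'
#' @param dataset_a,dataset_b Two [coexpr_dataset()]s.
#' @param out_dir Output directory.
#' @param merged_labels Optional named labels from a merged run (their
#'   gene universe is intersected with the consensus one).
#' @param variance_fraction Fraction of shared genes kept (default 0.25).
#' @param power,min_module_size,merge_cut_height,scale_toms,gap_fold,max_genes
#'   Passed to [run_consensus()].
#' @param seed Recorded in the summary.
#' @return Invisibly, the `consensus_report` plus `overlap` when computed.
#' @export
run_consensus_workflow <- function(dataset_a, dataset_b, out_dir,
                                   merged_labels = NULL,
                                   variance_fraction = 0.25, power = 6,
                                   min_module_size = 40,
                                   merge_cut_height = 0.25,
                                   scale_toms = TRUE,
                                   gap_fold = 4,
                                   max_genes = 6000, seed = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset_a <- log2_transform(dataset_a)
  dataset_b <- log2_transform(dataset_b)
  common <- intersect(rownames(dataset_a$values), rownames(dataset_b$values))
  a <- dataset_a$values[common, , drop = FALSE]
  b <- dataset_b$values[common, , drop = FALSE]
  v <- (apply(a, 1, stats::var) + apply(b, 1, stats::var)) / 2
  n_keep <- ceiling(variance_fraction * length(common))
  keep <- common[sort(order(-v, common)[seq_len(n_keep)])]
  dataset_a$values <- a[keep, , drop = FALSE]
  dataset_b$values <- b[keep, , drop = FALSE]

  report <- run_consensus(dataset_a, dataset_b, power = power,
                          min_module_size = min_module_size,
                          merge_cut_height = merge_cut_height,
                          scale_toms = scale_toms,
                          gap_fold = gap_fold,
                          max_genes = max_genes)

  part <- data.frame(gene = names(report$labels),
                     module = as.integer(report$labels),
                     color = report$colors)
  write_df_tsv(part, file.path(out_dir, "consensus_partition.tsv"))
  write_df_tsv(report$trait_a, file.path(out_dir, "module_trait_set1.tsv"))
  write_df_tsv(report$trait_b, file.path(out_dir, "module_trait_set2.tsv"))
  write_df_tsv(report$consensus_trait,
               file.path(out_dir, "module_trait_consensus.tsv"))
  pres <- report$preservation
  write_matrix_tsv(pres$preservation,
                   file.path(out_dir, "preservation_matrix.tsv"),
                   id_col = "module")

  overlap <- NULL
  if (!is.null(merged_labels)) {
    shared <- intersect(names(report$labels), names(merged_labels))
    overlap <- overlap_table(report$labels[shared], merged_labels[shared])
    oc <- as.data.frame.matrix(overlap$counts)
    oc <- cbind(consensus_module = rownames(oc), oc)
    write_df_tsv(oc, file.path(out_dir, "overlap_counts.tsv"))
  }

  summary <- list(seed = seed, n_genes = report$n_genes,
                  n_consensus_modules = length(unique(report$labels[report$labels > 0])),
                  preservation_density = pres$density,
                  na_trait_cells = sum(is.na(report$consensus_trait$r)))
  jsonlite::write_json(summary, file.path(out_dir, "consensus_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$overlap <- overlap
  invisible(report)
}
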