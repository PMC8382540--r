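# Standard module color vocabulary, assigned by module size rank; label 0
# ("grey") marks unassigned genes.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
  "sienna3", "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3")

#' Color names for module labels
#'
#' @param labels Integer module labels (0 = unassigned).
#' @return Character vector of color names ("grey" for 0).
#' @export
module_colors <- function(labels) {
  out <- rep("grey", length(labels))
  pos <- labels > 0
  idx <- labels[pos]
  if (any(idx > length(MODULE_COLORS)))
    idx <- ((idx - 1) %% length(MODULE_COLORS)) + 1
  out[pos] <- MODULE_COLORS[idx]
  names(out) <- names(labels)
  out
}

#' Re-rank module labels by decreasing module size
#'
#' Module ids are made contiguous from 1 in order of decreasing size;
#' size ties break by the smallest original label. Label 0 is preserved.
#'
#' @param labels Integer module labels.
#' @return Relabeled integer vector (names preserved).
#' @export
relabel_by_size <- function(labels) {
  pos <- labels[labels > 0]
  if (length(pos) == 0) return(labels)
  sizes <- table(pos)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- labels
  out[labels > 0] <- map[as.character(pos)]
  storage.mode(out) <- "integer"
  names(out) <- names(labels)
  out
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param diss Symmetric dissimilarity matrix with zero diagonal.
#' @return An `hclust` tree.
#' @export
average_linkage <- function(diss) {
  if (!isSymmetric(unname(diss), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Cut a dendrogram into modules of a minimum size
#'
#' A tree-based dynamic cut by recursive branch decomposition, equivalent
#' to breaking dendrogram merges in decreasing height order. Starting from
#' the root, the procedure descends: where both sub-branches hold at least
#' `min_module_size` leaves the branch splits and each side is decomposed
#' in turn; where only one side does, the descent continues into it and
#' the small remainder (loose genes and undersized branches chained onto
#' the tree) is left unassigned; where neither side does, the branch is a
#' candidate module. A candidate is kept whole unless a dominant gap --
#' at least a `gap_fold`-fold jump in merge similarity (headroom below the
#' tree's top height, examined on the log scale because topological
#' overlap compresses dissimilarities toward 1) -- separates a tight core
#' from loosely attached material, in which case only a module-sized core
#' is kept (and nothing, if no such core remains). Genuinely homogeneous
#' branches have a continuous height spectrum, show no such gap, and are
#' never eroded; large homogeneous branches may split into several parts,
#' which the downstream eigengene merge ([merge_close_modules()])
#' reunites. Clusters below `min_module_size` end up unassigned (label 0)
#' and surviving modules are relabeled by decreasing size.
#'
#' @param dendrogram An `hclust` tree (from [average_linkage()]).
#' @param min_module_size Minimum genes per module (default 40).
#' @param gap_fold Merge-similarity fold change defining a dominant gap
#'   (default 4).
#' @return Named integer labels, 0 = unassigned.
#' @export
cut_tree_dynamic <- function(dendrogram, min_module_size = 40,
                             gap_fold = 4) {
  n <- length(dendrogram$order)
  if (min_module_size > n)
    warning("min_module_size exceeds the gene count; all genes unassigned")
  merge <- dendrogram$merge
  height <- dendrogram$height
  n_nodes <- nrow(merge)
  # leaves and internal merges of each subtree (children precede parents)
  leaves <- vector("list", n_nodes)
  internals <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    ch <- merge[i, ]
    leaves[[i]] <- c(if (ch[1] < 0) -ch[1] else leaves[[ch[1]]],
                     if (ch[2] < 0) -ch[2] else leaves[[ch[2]]])
    internals[[i]] <- c(i, if (ch[1] > 0) internals[[ch[1]]],
                        if (ch[2] > 0) internals[[ch[2]]])
  }
  labels <- integer(n)
  next_label <- 0L
  node_size <- function(nd) if (nd < 0) 1L else length(leaves[[nd]])
  node_leaves <- function(nd) if (nd < 0) -nd else leaves[[nd]]
  label_whole <- function(nd) {
    next_label <<- next_label + 1L
    labels[node_leaves(nd)] <<- next_label
  }
  # maximal subnodes of `node` merged strictly below height h
  components_below <- function(node, h) {
    out <- list()
    todo <- node
    while (length(todo) > 0) {
      nd <- todo[[length(todo)]]
      todo <- todo[-length(todo)]
      if (nd < 0 || height[nd] < h) out[[length(out) + 1L]] <- nd
      else todo <- c(todo, merge[nd, 1], merge[nd, 2])
    }
    out
  }
  # Candidate module: keep whole, or shed loosely attached material.
  # Loose genes join a tight core with far less merge similarity
  # (headroom below the tree's top height) than the core's own merges, so
  # a dominant fold-change gap in the log headroom spectrum marks the
  # core/junk boundary; a homogeneous branch has a continuous spectrum
  # and shows no such gap. When shedding leaves no module-sized core the
  # whole branch is deemed loose and stays unassigned.
  h_ref <- max(height)
  h_eps <- max(1e-3 * (h_ref - min(height)), 1e-12)
  finalize <- function(node) {
    hs <- sort(height[internals[[node]]])    # ascending: core -> junk
    if (length(hs) < 4) { label_whole(node); return(invisible()) }
    log_s <- log(h_ref - hs + h_eps)         # decreasing in hs
    gaps <- log_s[-length(log_s)] - log_s[-1]
    i_gap <- which.max(gaps)
    if (gaps[i_gap] >= log(gap_fold)) {
      h_cut <- h_ref + h_eps - exp((log_s[i_gap] + log_s[i_gap + 1]) / 2)
      comps <- components_below(node, h_cut)
      sizes <- vapply(comps, node_size, 1L)
      core <- which.max(sizes)
      if (sizes[core] >= min_module_size) label_whole(comps[[core]])
      # else: the branch has no module-sized core; all leaves stay grey
      return(invisible())
    }
    label_whole(node)
  }
  stack <- if (n >= 2 && n >= min_module_size) n_nodes else integer(0)
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    cur <- node
    repeat {
      ch <- merge[cur, ]
      s1 <- node_size(ch[1])
      s2 <- node_size(ch[2])
      if (s1 >= min_module_size && s2 >= min_module_size) {
        for (child in ch) {
          if (child > 0) stack[[length(stack) + 1L]] <- child
          else label_whole(child)
        }
        break
      } else if (s1 >= min_module_size && ch[1] > 0) {
        cur <- ch[1]
      } else if (s2 >= min_module_size && ch[2] > 0) {
        cur <- ch[2]
      } else {
        finalize(node)
        break
      }
    }
  }
  sizes <- table(labels[labels > 0])
  small <- as.integer(names(sizes)[sizes < min_module_size])
  labels[labels %in% small] <- 0L
  names(labels) <- dendrogram$labels
  relabel_by_size(labels)
}

#' Module eigengenes
#'
#' Each module's eigengene is the first right singular vector of its
#' standardized (per-gene z-scored) expression submatrix, sign-aligned so
#' its correlation with the module's mean expression profile is
#' non-negative. Rows of the returned matrix are unit-norm. The explained
#' variance fraction is the first squared singular value over the total.
#'
#' @param dataset A [coexpr_dataset()] or genes x samples matrix.
#' @param labels Integer module labels over the dataset's genes
#'   (0 = unassigned, skipped).
#' @return List with `values` (modules x samples matrix, rownames
#'   `"ME<id>"`) and `var_explained` (named numeric).
#' @export
module_eigengenes <- function(dataset, labels) {
  m <- if (inherits(dataset, "coexpr_dataset")) dataset$values else dataset
  stopifnot(length(labels) == nrow(m))
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no assigned modules")
  me <- matrix(NA_real_, length(mods), ncol(m),
               dimnames = list(paste0("ME", mods), colnames(m)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    sub <- m[labels == mods[i], , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    v1 <- sv$v[, 1]
    avg <- colMeans(z)
    if (stats::sd(avg) > 0 && stats::cor(v1, avg) < 0) v1 <- -v1
    me[i, ] <- v1
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(values = me, var_explained = ve)
}

#' Merge modules with highly correlated eigengenes
#'
#' Eigengenes are clustered by average linkage on `1 - cor(ME)`; clusters
#' joined below `cut_height` are merged (so modules whose eigengene
#' correlation exceeds `1 - cut_height` end up together), eigengenes are
#' recomputed, and the procedure iterates to a fixed point. After
#' convergence no pair of module eigengenes correlates above
#' `1 - cut_height`.
#'
#' @param dataset A [coexpr_dataset()] or matrix.
#' @param labels Integer module labels (0 = unassigned).
#' @param cut_height Dendrogram height below which modules merge
#'   (default 0.25).
#' @return List with `labels` (relabeled by size) and `eigengenes`
#'   (the [module_eigengenes()] result for the final labels).
#' @export
merge_close_modules <- function(dataset, labels, cut_height = 0.25) {
  m <- if (inherits(dataset, "coexpr_dataset")) dataset$values else dataset
  labels <- relabel_by_size(labels)
  max_iter <- max(labels) + 1L
  for (iter in seq_len(max_iter)) {
    me <- module_eigengenes(m, labels)
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    d <- 1 - stats::cor(t(me$values))
    grp <- stats::cutree(average_linkage(d), h = cut_height)
    if (length(unique(grp)) == length(mods)) break
    map <- stats::setNames(grp, mods)
    labels[labels > 0] <- map[as.character(labels[labels > 0])]
    storage.mode(labels) <- "integer"
    labels <- relabel_by_size(labels)
  }
  list(labels = labels, eigengenes = module_eigengenes(m, labels))
}
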