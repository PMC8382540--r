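#' Expression dataset container
#'
#' A `coexpr_dataset` bundles a log2-scale expression matrix (genes in rows,
#' samples in columns) with per-sample group and batch labels. Gene and
#' sample identifiers live in the dimnames of `values`.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids). No missing values allowed.
#' @param group Character or factor, one of `"case"`/`"control"` per sample.
#' @param batch Character vector of batch identifiers, one per sample.
#' @return An object of class `coexpr_dataset`: a list with elements
#'   `values`, `group`, `batch`.
#' @export
coexpr_dataset <- function(values, group, batch) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at gene ", rownames(values)[bad[1]],
         ", sample ", colnames(values)[bad[2]],
         " (inputs must be complete; imputation is out of scope)")
  }
  group <- as.character(group)
  batch <- as.character(batch)
  if (length(group) != ncol(values) || length(batch) != ncol(values))
    stop("`group` and `batch` must have one entry per sample")
  if (!all(group %in% c("case", "control")))
    stop("`group` entries must be 'case' or 'control'")
  structure(list(values = values, group = group, batch = batch),
            class = "coexpr_dataset")
}

#' @export
print.coexpr_dataset <- function(x, ...) {
  cat("coexpr_dataset: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  groups: ", sum(x$group == "case"), " case / ",
      sum(x$group == "control"), " control\n", sep = "")
  cat("  batches: ", paste(unique(x$batch), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.coexpr_dataset <- function(x) dim(x$values)

#' Case-indicator trait vector of a dataset
#'
#' @param dataset A `coexpr_dataset`.
#' @return Named numeric vector, 1 for case samples, 0 for controls.
#' @export
trait_vector <- function(dataset) {
  stopifnot(inherits(dataset, "coexpr_dataset"))
  out <- as.numeric(dataset$group == "case")
  names(out) <- colnames(dataset$values)
  out
}

read_numeric_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an id column plus >=1 sample column in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-numeric value in ", path, " at row id '", ids[bad[1, 1]],
           "', column '", colnames(df)[-1][bad[1, 2]], "'")
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  m
}

#' Read an expression matrix with sample annotation
#'
#' The expression TSV has gene ids in the first column and sample ids in the
#' header. The annotation TSV has columns `sample`, `group`, `batch`;
#' annotation rows are aligned to matrix columns by sample id, never by
#' position.
#'
#' @param path Expression TSV path.
#' @param annotation_path Sample annotation TSV path; if `NULL` a bare
#'   numeric matrix (e.g. a probe matrix awaiting collapse) is returned.
#' @return A `coexpr_dataset`, or a matrix when `annotation_path` is `NULL`.
#' @export
read_expression <- function(path, annotation_path = NULL) {
  m <- read_numeric_table(path)
  if (is.null(annotation_path)) return(m)
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample", "group", "batch")
  if (!all(need %in% colnames(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(m), ann$sample)
  if (length(missing) > 0)
    stop("samples present in matrix but absent from annotation: ",
         paste(missing, collapse = ", "))
  idx <- match(colnames(m), ann$sample)
  coexpr_dataset(m, group = ann$group[idx], batch = ann$batch[idx])
}

fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6))

write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), apply(m, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dataset as expression + annotation TSVs
#'
#' @param dataset A `coexpr_dataset`.
#' @param expr_path,annotation_path Output paths.
#' @return Invisibly, the expression path.
#' @export
write_expression <- function(dataset, expr_path, annotation_path) {
  stopifnot(inherits(dataset, "coexpr_dataset"))
  write_matrix_tsv(dataset$values, expr_path)
  ann <- data.frame(sample = colnames(dataset$values),
                    group = dataset$group, batch = dataset$batch)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}
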