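#' Build standardized expression features for one focal cell type
#'
#' Transforms a genes x cell-types mean-expression matrix into the two
#' per-gene covariates of the feature-level prior: the focal cell type's
#' expression and a baseline shared by all fits. Expression is first
#' log-transformed, `f = ln(1 + E)`, to bound the leverage of highly
#' expressed genes; the baseline is the per-gene mean of `f` across all cell
#' types. Both columns are then z-scored across genes (sample standard
#' deviation). A constant column cannot be standardized and maps to all
#' zeros with its degenerate flag set.
#'
#' @param expr Expression input: a numeric matrix with gene row names and
#'   cell-type column names, or a data frame with a gene-identifier column.
#'   Values must be nonnegative.
#' @param focal_cell_type Column label of the focal cell type.
#' @return A tibble with columns `gene_id`, `x_celltype`, `x_baseline`,
#'   carrying attributes `focal_cell_type` and `degenerate` (TRUE if either
#'   feature column was constant).
#' @export
build_features <- function(expr, focal_cell_type) {
  expr <- as_expression_matrix(expr)
  if (length(focal_cell_type) != 1L || !focal_cell_type %in% colnames(expr)) {
    abort(sprintf("unknown cell type %s; available: %s",
                  paste(focal_cell_type, collapse = ", "),
                  paste(colnames(expr), collapse = ", ")))
  }
  f <- log1p(expr)
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      structure(rep(0, length(x)), degenerate = TRUE)
    } else {
      structure((x - mean(x)) / s, degenerate = FALSE)
    }
  }
  xc <- zscore(f[, focal_cell_type])
  xb <- zscore(rowMeans(f))
  out <- tibble(
    gene_id = rownames(expr),
    x_celltype = as.numeric(xc),
    x_baseline = as.numeric(xb)
  )
  attr(out, "focal_cell_type") <- focal_cell_type
  attr(out, "degenerate") <- attr(xc, "degenerate") || attr(xb, "degenerate")
  out
}
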