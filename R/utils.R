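# Numerically stable log(exp(a) + exp(b)), vectorised; tolerates -Inf in
# either argument (returns the other).
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  s <- pmin(a, b)
  out <- m + log1p(exp(s - m))
  both_inf <- is.infinite(m) & m < 0
  out[both_inf] <- -Inf
  out
}

# log(sum(exp(x))) for a vector.
logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# Strip a leading "chr" prefix so that both chromosome-name dialects match.
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

# Accept a genes x cell-types expression input as either a numeric matrix with
# rownames, or a data frame whose first column (or a column named gene_id)
# holds gene identifiers. Returns a named numeric matrix.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    id_col <- if ("gene_id" %in% names(expr)) "gene_id" else names(expr)[1L]
    ids <- as.character(expr[[id_col]])
    mat <- as.matrix(expr[setdiff(names(expr), id_col)])
    rownames(mat) <- ids
    expr <- mat
  }
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix or a data frame of gene_id + numeric columns.")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` must carry gene identifiers as row names and cell-type labels as column names.")
  }
  if (anyDuplicated(rownames(expr))) abort("gene identifiers in `expr` must be unique.")
  if (anyDuplicated(colnames(expr))) abort("cell-type labels in `expr` must be unique.")
  if (any(expr < 0)) abort("`expr` must not contain negative expression values.")
  expr
}

validate_sumstats <- function(stats) {
  required <- c("variant_id", "chrom", "pos", "beta", "se")
  missing <- setdiff(required, names(stats))
  if (length(missing) > 0) {
    abort(sprintf("summary statistics are missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(stats) > 0) {
    if (anyDuplicated(stats$variant_id)) {
      abort("duplicate variant_id in summary statistics; ambiguous input.")
    }
    if (any(!is.finite(stats$se) | stats$se <= 0)) abort("`se` must be > 0 for every variant.")
    if (any(stats$pos < 1)) abort("`pos` must be >= 1 (1-based coordinates).")
  }
  invisible(stats)
}

validate_gene_annotation <- function(genes) {
  required <- c("gene_id", "chrom", "tss")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    abort(sprintf("gene annotation is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in gene annotation.")
  if (nrow(genes) > 0 && any(genes$tss < 1)) abort("`tss` must be >= 1 (1-based coordinates).")
  invisible(genes)
}
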