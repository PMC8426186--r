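#' Read GWAS summary statistics
#'
#' Reads a tab-separated table with header columns `variant_id`, `chrom`,
#' `pos`, `beta` (log odds ratio) and `se`; extra columns are ignored.
#' Validates that standard errors are positive, positions 1-based, and
#' variant identifiers unique (duplicates are a hard error: the input is
#' ambiguous, not deduplicated).
#'
#' @param path Path to the tab-separated file.
#' @return A tibble of summary statistics.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) abort(sprintf("summary-statistics file not found: %s", path))
  stats <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sumstats(stats)
  stats$chrom <- as.character(stats$chrom)
  stats$pos <- as.integer(stats$pos)
  stats[c("variant_id", "chrom", "pos", "beta", "se")]
}

#' Read a gene annotation with transcription start sites
#'
#' Accepts either a tab-separated table with columns `gene_id`, `chrom`,
#' `strand`, `tss`, or a GTF file (extension `.gtf` or `.gtf.gz`; requires
#' the rtracklayer package), from which gene features are taken and the TSS
#' resolved by strand: the feature start for `+` genes, the feature end for
#' `-` genes.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("gene annotation file not found: %s", path))
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF requires the rtracklayer package; supply a TSV annotation instead.")
    }
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr[gr$type == "gene"])
    if (nrow(df) == 0) abort("GTF contains no 'gene' features.")
    genes <- tibble(
      gene_id = as.character(df$gene_id),
      chrom = as.character(df$seqnames),
      strand = as.character(df$strand),
      tss = ifelse(df$strand == "-", df$end, df$start)
    )
  } else {
    genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!"strand" %in% names(genes)) genes$strand <- "+"
  }
  validate_gene_annotation(genes)
  genes$chrom <- as.character(genes$chrom)
  genes$tss <- as.integer(genes$tss)
  genes[c("gene_id", "chrom", "strand", "tss")]
}

#' Read a genes x cell-types mean-expression matrix
#'
#' Accepts either a CSV whose first column holds gene identifiers and whose
#' remaining columns are cell types, or a MatrixMarket triplet file plus
#' plain-text row (gene) and column (cell type) label files, one label per
#' line.
#'
#' @param path Path to the CSV or `.mtx` file.
#' @param row_labels,col_labels Paths to label files; required for
#'   MatrixMarket input, ignored for CSV.
#' @return A numeric matrix, genes in rows, cell types in columns.
#' @export
read_expression <- function(path, row_labels = NULL, col_labels = NULL) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(row_labels) || is.null(col_labels)) {
      abort("MatrixMarket input requires `row_labels` and `col_labels` files.")
    }
    mat <- as.matrix(Matrix::readMM(path))
    rownames(mat) <- readLines(row_labels)
    colnames(mat) <- readLines(col_labels)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    mat <- as.matrix(df[-1L])
    rownames(mat) <- as.character(df[[1L]])
  }
  as_expression_matrix(mat)
}

#' Read a samples x cell-types count table
#'
#' CSV with sample identifiers in the first column and one column of
#' nonnegative integer counts per cell type.
#'
#' @param path Path to the CSV file.
#' @return An integer matrix, samples in rows, cell types in columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("counts file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(df[-1L])
  rownames(mat) <- as.character(df[[1L]])
  if (any(mat < 0) || any(mat != round(mat))) {
    abort("counts must be nonnegative integers.")
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Read per-sample metadata
#'
#' CSV keyed by a `sample_id` column (or the first column), one column per
#' categorical factor; all factor columns are read as character.
#'
#' @param path Path to the CSV file.
#' @return A tibble with a `sample_id` column plus one column per factor.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  md <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"sample_id" %in% names(md)) names(md)[1L] <- "sample_id"
  if (anyDuplicated(md$sample_id)) abort("duplicate sample_id in metadata.")
  md
}

write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
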