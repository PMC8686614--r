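#' Read a CellRanger-style Matrix Market triplet
#'
#' Reads a sparse feature-by-cell UMI count matrix stored as a Matrix Market
#' file with companion feature and barcode TSV files (one ID per line; extra
#' columns after the first are ignored).
#'
#' @param mtx_path Path to the `.mtx` file (features x cells).
#' @param features_path Path to the feature ID file (row IDs).
#' @param barcodes_path Path to the cell barcode file (column IDs).
#' @return A `dgCMatrix` with feature IDs as rownames and cell barcodes as
#'   colnames.
#' @export
read_mtx_triplet <- function(mtx_path, features_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  cells <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feats) || ncol(m) != length(cells)) {
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match ID files (", length(feats), " features, ",
         length(cells), " cells)")
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(feats, cells)
  m
}

#' Write a matrix as a CellRanger-style Matrix Market triplet
#'
#' @param m Matrix (dense or sparse) with row and column names.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix; writes `<prefix>.mtx`,
#'   `<prefix>.features.tsv`, `<prefix>.barcodes.tsv`.
#' @return Invisibly, the three paths written.
#' @export
write_mtx_triplet <- function(m, dir, prefix = "matrix") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  paths <- file.path(dir, paste0(prefix, c(".mtx", ".features.tsv", ".barcodes.tsv")))
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), paths[1])
  writeLines(rownames(m), paths[2])
  writeLines(colnames(m), paths[3])
  invisible(paths)
}

#' Threshold gRNA UMI counts into binary assignments
#'
#' A gRNA is called present in a cell when its UMI count reaches `threshold`
#' (inclusive). The default of 5 UMIs is a conservative knob that suppresses
#' ambient-gRNA background; it is configurable and makes no claim about any
#' particular published screen.
#'
#' @param umi_counts gRNA-by-cell matrix of non-negative integer UMI counts.
#' @param threshold Positive integer; counts `>= threshold` are assignments.
#' @return A binary gRNA-by-cell matrix (sparse if the input was sparse) with
#'   attribute `threshold` recording the rule. gRNAs with zero assigned cells
#'   trigger a warning (pair-level tests on them will fail downstream).
#' @export
assign_grnas <- function(umi_counts, threshold = 5) {
  stopifnot(length(threshold) == 1, threshold >= 1, threshold == round(threshold))
  if (any(umi_counts < 0)) stop("gRNA UMI counts must be non-negative")
  assign <- 1 * (umi_counts >= threshold)
  if (inherits(umi_counts, "Matrix")) {
    assign <- methods::as(Matrix::Matrix(assign, sparse = TRUE), "generalMatrix")
  }
  dimnames(assign) <- dimnames(umi_counts)
  n_cells <- Matrix::rowSums(assign)
  message(sprintf("assigned cells per gRNA: median %d, range %d-%d",
                  as.integer(median(n_cells)), as.integer(min(n_cells)),
                  as.integer(max(n_cells))))
  empty <- sum(n_cells == 0)
  if (empty > 0) {
    warning(empty, " gRNA(s) have zero assigned cells at threshold ", threshold)
  }
  attr(assign, "threshold") <- threshold
  assign
}

#' Compute per-cell technical covariates
#'
#' Builds the covariate table used to adjust both the expression model and the
#' gRNA propensity model: sequencing depth, number of expressed genes,
#' mitochondrial fraction, number of detected gRNAs (all log scale except
#' percent mito), plus batch.
#'
#' @param expr Gene-by-cell UMI count matrix with dimnames.
#' @param grna_assignments Binary gRNA-by-cell matrix (see [assign_grnas()])
#'   with the same cells in the same order.
#' @param mito_gene_ids Character vector of mitochondrial gene IDs (subset of
#'   `rownames(expr)`); may be empty.
#' @param batch Factor or character vector of batch labels, one per cell.
#' @return A data.frame with one row per cell, in matrix cell order:
#'   `cell_id`, `batch` (factor), `log_total_umis`, `log_n_genes_expressed`,
#'   `pct_mito` (0-100 scale), `log_n_grnas` (log1p, gRNA count can be zero).
#'   Cells with zero total UMIs are an error: filter them first.
#' @export
compute_cell_covariates <- function(expr, grna_assignments, mito_gene_ids = character(),
                                    batch = NULL) {
  n <- ncol(expr)
  if (!is.null(colnames(grna_assignments)) && !is.null(colnames(expr)) &&
      !identical(colnames(expr), colnames(grna_assignments))) {
    stop("expression and gRNA matrices have different cell ID order")
  }
  if (ncol(grna_assignments) != n) stop("cell count mismatch between matrices")
  if (is.null(batch)) batch <- rep("batch1", n)
  if (length(batch) != n) stop("batch labels must have one entry per cell")
  if (!all(mito_gene_ids %in% rownames(expr))) {
    stop("mito_gene_ids contains IDs absent from the expression matrix")
  }
  total <- Matrix::colSums(expr)
  if (any(total == 0)) {
    stop(sum(total == 0), " cell(s) have zero total UMIs; drop them before ",
         "computing covariates")
  }
  n_genes <- Matrix::colSums(expr > 0)
  mito <- if (length(mito_gene_ids)) {
    Matrix::colSums(expr[mito_gene_ids, , drop = FALSE])
  } else rep(0, n)
  data.frame(
    cell_id = if (!is.null(colnames(expr))) colnames(expr) else paste0("cell", seq_len(n)),
    batch = factor(batch),
    log_total_umis = log(total),
    log_n_genes_expressed = log(n_genes),
    pct_mito = 100 * mito / total,
    log_n_grnas = log1p(Matrix::colSums(grna_assignments)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Build the full-rank covariate design matrix Z
#'
#' One-hot encodes categorical columns with the first level dropped as the
#' reference (full-rank design; the GLMs add their own intercept) and keeps
#' numeric columns as-is.
#'
#' @param covariates Data.frame as returned by [compute_cell_covariates()] or
#'   any per-cell table; a `cell_id` column, if present, is excluded.
#' @return Numeric matrix with one row per cell.
#' @export
covariate_matrix <- function(covariates) {
  df <- covariates[, setdiff(names(covariates), "cell_id"), drop = FALSE]
  # drop constant columns (single batch, all-zero pct_mito, ...): they carry
  # no information and would break the full-rank requirement
  keep <- vapply(df, function(col) {
    if (is.factor(col) || is.character(col)) nlevels(droplevels(factor(col))) > 1
    else length(unique(col)) > 1
  }, logical(1))
  df <- df[, keep, drop = FALSE]
  if (ncol(df) == 0) return(matrix(numeric(0), nrow = nrow(covariates), ncol = 0))
  mm <- model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Read / write a per-cell covariate table
#'
#' TSV with header, cell ID in the first column; round-trips the table
#' written by [write_covariates()].
#'
#' @param path File path.
#' @return Data.frame with `batch` restored as a factor.
#' @export
read_covariates <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1] <- "cell_id"
  if ("batch" %in% names(df)) df$batch <- factor(df$batch)
  df
}

#' @param covariates Data.frame, one row per cell, cell ID first.
#' @rdname read_covariates
#' @export
write_covariates <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
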