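#' Construct an expression matrix
#'
#' The package's core container: a genes x cells matrix of UMI counts (raw) or
#' depth-normalized counts, with unique gene and cell identifiers. Dense input
#' is stored sparse when fewer than half the entries are non-zero; behaviour is
#' value-identical either way.
#'
#' @param values Numeric genes x cells matrix (base matrix or a `Matrix`
#'   sparse matrix), non-negative. Row names are taken as gene ids and column
#'   names as cell ids unless `gene_ids`/`cell_ids` are given.
#' @param gene_ids,cell_ids Optional character vectors of unique identifiers.
#' @param normalized Logical; `TRUE` once each cell has been scaled to a fixed
#'   total (see [normalize_depth()]).
#' @param target_depth Reads per cell after normalization (only meaningful when
#'   `normalized = TRUE`).
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                              normalized = FALSE, target_depth = NA_real_) {
  if (is.data.frame(values)) values <- as.matrix(values)
  gene_ids <- as.character(gene_ids %||% rownames(values))
  cell_ids <- as.character(cell_ids %||% colnames(values))
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    abort("gene_ids/cell_ids lengths must match the matrix dimensions",
          class = "memlin_validation_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort("duplicate gene identifiers", class = "memlin_validation_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort("duplicate cell identifiers", class = "memlin_validation_error")
  }
  if (length(values) && min(values, na.rm = TRUE) < 0) {
    abort("negative expression values are not allowed",
          class = "memlin_validation_error")
  }
  dense_frac <- if (length(values)) Matrix::nnzero(values) / length(values) else 1
  if (dense_frac < 0.5) {
    values <- methods::as(methods::as(Matrix::Matrix(values), "generalMatrix"),
                          "CsparseMatrix")
  } else {
    values <- as.matrix(values)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         normalized = isTRUE(normalized), target_depth = target_depth),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts",
              if (x$normalized) sprintf(", target depth %g", x$target_depth) else ""))
  invisible(x)
}

#' Extract the values of an expression matrix as a dense base matrix
#'
#' @param m An `expression_matrix`.
#' @param genes,cells Optional identifier vectors to subset to.
#' @return A dense numeric matrix (genes x cells).
#' @export
as_dense <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  as.matrix(v)
}

#' Per-cell total counts
#'
#' @param m An `expression_matrix`.
#' @return Named numeric vector of column totals.
#' @export
cell_totals <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  setNames(Matrix::colSums(m$values), m$cell_ids)
}

#' Scale every cell to a fixed sequencing depth
#'
#' Reads-per-million-style normalization: each cell's counts are multiplied by
#' `target_depth / total`, so every cell with at least one read sums to
#' `target_depth`. The default of 40,000 makes one normalized count roughly one
#' read for typical 10x libraries. Cells with zero total are left all-zero,
#' kept in the matrix (so annotations stay aligned) and recorded in the
#' `zero_depth_cells` attribute; downstream correlation steps skip them.
#'
#' @param m A raw `expression_matrix`.
#' @param target_depth Positive total to scale each cell to.
#' @return A normalized `expression_matrix`.
#' @export
normalize_depth <- function(m, target_depth = 40000) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$normalized) {
    abort("matrix is already normalized", class = "memlin_parameter_error")
  }
  if (!is.numeric(target_depth) || length(target_depth) != 1 || target_depth <= 0) {
    abort("target_depth must be a single positive number",
          class = "memlin_parameter_error")
  }
  totals <- cell_totals(m)
  zero <- names(totals)[totals == 0]
  scale <- ifelse(totals > 0, target_depth / totals, 0)
  values <- m$values %*% Matrix::Diagonal(x = scale)
  if (is.matrix(m$values)) values <- as.matrix(values)
  dimnames(values) <- dimnames(m$values)
  out <- expression_matrix(values, m$gene_ids, m$cell_ids,
                           normalized = TRUE, target_depth = target_depth)
  attr(out, "zero_depth_cells") <- zero
  if (length(zero)) {
    warn(sprintf("%d cell(s) with zero total counts kept all-zero: %s",
                 length(zero), paste(head(zero, 5), collapse = ", ")))
  }
  out
}

#' Cells excluded from correlation computations
#'
#' @param m An `expression_matrix`.
#' @return Character vector of cell ids with zero raw total (empty if none).
#' @export
zero_depth_cells <- function(m) {
  attr(m, "zero_depth_cells") %||% character()
}
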