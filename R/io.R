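#' Read a count matrix
#'
#' Two on-disk layouts are supported: the 10x-style MatrixMarket triple (a
#' directory holding `matrix.mtx`, `features.tsv` and `barcodes.tsv`, each
#' optionally gzipped) and a dense delimited table with gene ids in the first
#' column and cell ids in the header row.
#'
#' @param path Directory (for `format = "mtx"`) or file (for `format = "csv"`).
#' @param format `"mtx"` for the MatrixMarket triple, `"csv"` for a dense
#'   CSV/TSV table (the delimiter is taken from the file extension).
#' @param transposed Set `TRUE` if a dense table is cells x genes; orientation
#'   is never guessed.
#' @return A raw (`normalized = FALSE`) [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("mtx", "csv"), transposed = FALSE) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- .find_triple_file(path, "matrix.mtx")
    feats <- .find_triple_file(path, "features.tsv", alt = "genes.tsv")
    bcs <- .find_triple_file(path, "barcodes.tsv")
    values <- Matrix::readMM(mtx)
    gene_ids <- readr::read_tsv(feats, col_names = FALSE, col_types = readr::cols(),
                                progress = FALSE)[[1]]
    cell_ids <- readr::read_tsv(bcs, col_names = FALSE, col_types = readr::cols(),
                                progress = FALSE)[[1]]
    if (length(gene_ids) != nrow(values)) {
      abort(sprintf("feature file %s lists %d genes but matrix has %d rows",
                    feats, length(gene_ids), nrow(values)),
            class = "memlin_format_error")
    }
    if (length(cell_ids) != ncol(values)) {
      abort(sprintf("barcode file %s lists %d cells but matrix has %d columns",
                    bcs, length(cell_ids), ncol(values)),
            class = "memlin_format_error")
    }
    return(expression_matrix(values, gene_ids, cell_ids))
  }
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  if (transposed) values <- t(values)
  expression_matrix(values)
}

.find_triple_file <- function(dir, name, alt = NULL) {
  for (cand in c(name, paste0(name, ".gz"),
                 alt, if (!is.null(alt)) paste0(alt, ".gz"))) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  abort(sprintf("no %s found under %s", name, dir), class = "memlin_format_error")
}

#' Write a count matrix
#'
#' Inverse of [read_matrix()]: emits either the MatrixMarket triple into a
#' directory or a dense delimited table. Integer counts round-trip exactly.
#'
#' @param m An [expression_matrix()].
#' @param path Output directory (`"mtx"`) or file (`"csv"`).
#' @inheritParams read_matrix
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("mtx", "csv")) {
  stopifnot(inherits(m, "expression_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    sp <- methods::as(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(id = m$gene_ids), file.path(path, "features.tsv"),
                     col_names = FALSE)
    readr::write_tsv(tibble(id = m$cell_ids), file.path(path, "barcodes.tsv"),
                     col_names = FALSE)
  } else {
    tab <- as_tibble(as_dense(m), rownames = "gene_id")
    if (grepl("\\.csv$", path)) readr::write_csv(tab, path)
    else readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a cell annotation table
#'
#' A two-column, tab-separated file with a header: `cell_id<TAB>label`. Cells
#' absent from the file are simply unannotated; duplicated cell ids are an
#' error.
#'
#' @param path TSV file.
#' @param kind `"lineage"` for a cell-to-lineage map, `"cell_type"` for a
#'   cell-to-type map.
#' @return A tibble with columns `cell_id` and `lineage_id` (or `cell_type`),
#'   of class `lineage_partition` when `kind = "lineage"`.
#' @export
read_annotation <- function(path, kind = c("lineage", "cell_type")) {
  kind <- match.arg(kind)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2) {
    abort("annotation file must have two columns (cell_id, label)",
          class = "memlin_format_error")
  }
  tab <- tab[, 1:2]
  names(tab) <- c("cell_id", if (kind == "lineage") "lineage_id" else "cell_type")
  if (anyDuplicated(tab$cell_id)) {
    abort("duplicated cell_id rows in annotation file",
          class = "memlin_validation_error")
  }
  if (kind == "cell_type" && any(!nzchar(tab$cell_type) | is.na(tab$cell_type))) {
    abort("cell_type labels must be non-empty", class = "memlin_validation_error")
  }
  if (kind == "lineage") as_lineage_partition(tab, source = "ground_truth") else tab
}

#' Coerce to a lineage partition
#'
#' A lineage partition maps cells to lineages (clones); it may be partial —
#' unannotated cells are simply absent. Represented as a tibble with columns
#' `cell_id`, `lineage_id` and a `source` attribute saying whether it is
#' ground truth or predicted.
#'
#' @param x A data frame with columns `cell_id`, `lineage_id`, or a named
#'   vector of lineage ids keyed by cell id.
#' @param source `"ground_truth"` or `"predicted"`.
#' @return A `lineage_partition` tibble.
#' @export
as_lineage_partition <- function(x, source = c("ground_truth", "predicted")) {
  source <- match.arg(source)
  if (!is.data.frame(x)) {
    x <- tibble(cell_id = names(x), lineage_id = as.character(unname(x)))
  }
  x <- as_tibble(x)[, c("cell_id", "lineage_id")]
  x$cell_id <- as.character(x$cell_id)
  x$lineage_id <- as.character(x$lineage_id)
  if (anyDuplicated(x$cell_id)) {
    abort("a cell cannot belong to two lineages", class = "memlin_validation_error")
  }
  structure(x, source = source,
            class = c("lineage_partition", class(x)))
}

#' Sizes of the lineages in a partition
#'
#' @param lp A `lineage_partition`.
#' @return A tibble with columns `lineage_id` and `size`.
#' @export
lineage_sizes <- function(lp) {
  lp |>
    as_tibble() |>
    dplyr::count(.data$lineage_id, name = "size") |>
    arrange(.data$lineage_id)
}
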