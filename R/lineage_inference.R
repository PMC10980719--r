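#' Parameters of the repeated iterative clustering predictor
#'
#' @param sampling_fraction Fraction of the selected genes drawn (without
#'   replacement) for each prediction repetition; in (0, 1].
#' @param n_repetitions Number of prediction repetitions; the confidence level
#'   of a cell pair is the number of repetitions in which it co-clustered.
#' @param cluster_cut Number of clusters each cluster is split into per
#'   iteration.
#' @param lineage_size_min,lineage_size_max Terminal cluster size range:
#'   iteration stops for clusters of at most `lineage_size_max` cells.
#'   `lineage_size_min` is used for reporting only.
#' @param seed Integer seed; all randomness in [predict_lineages()] flows from
#'   it.
#' @return A `prediction_params` list.
#' @export
prediction_params <- function(sampling_fraction = 0.75, n_repetitions = 100,
                              cluster_cut = 2, lineage_size_min = 2,
                              lineage_size_max = 3, seed = 1) {
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    abort("sampling_fraction must be in (0, 1]", class = "memlin_parameter_error")
  }
  if (n_repetitions < 1) abort("n_repetitions must be >= 1",
                               class = "memlin_parameter_error")
  if (cluster_cut < 2) abort("cluster_cut must be >= 2",
                             class = "memlin_parameter_error")
  if (lineage_size_min < 2 || lineage_size_max < lineage_size_min) {
    abort("need 2 <= lineage_size_min <= lineage_size_max",
          class = "memlin_parameter_error")
  }
  structure(list(sampling_fraction = sampling_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 cluster_cut = as.integer(cluster_cut),
                 lineage_size_min = as.integer(lineage_size_min),
                 lineage_size_max = as.integer(lineage_size_max),
                 seed = as.integer(seed)),
            class = "prediction_params")
}

#' Pearson correlation distance between cells
#'
#' `d[i, j] = 1 - cor(cell_i, cell_j)` over the given genes, so d lies in
#' \[0, 2\] with 0 for identical profiles. A cell with zero variance over the
#' gene subset has undefined correlations; these are set to 0 (distance 1) with
#' a warning, so the cell still participates rather than being dropped.
#'
#' @param m An [expression_matrix()].
#' @param genes,cells Optional id vectors restricting the computation.
#' @param log1p Correlate `log(1 + x)` instead of x.
#' @return A symmetric cells x cells distance matrix.
#' @export
correlation_distance <- function(m, genes = NULL, cells = NULL, log1p = FALSE) {
  v <- as_dense(m, genes = genes, cells = cells)
  if (ncol(v) < 2) abort("need at least 2 cells", class = "memlin_data_error")
  if (nrow(v) < 1) abort("gene subset is empty", class = "memlin_data_error")
  if (log1p) v <- log1p(v)
  suppressWarnings(r <- cor(v))
  if (anyNA(r)) {
    warn("cells with zero variance over the gene subset: correlation set to 0")
    r[is.na(r)] <- 0
  }
  d <- 1 - r
  diag(d) <- 0
  d
}

# Recursive Ward splitting of one gene subsample: returns an integer matrix of
# co-clustered cell index pairs (columns i, j with i < j).
.iterative_split <- function(v_cells, params) {
  n_max <- params$lineage_size_max
  pairs <- vector("list", 0)
  recurse <- function(idx) {
    if (length(idx) <= n_max) {
      if (length(idx) >= 2) {
        pairs[[length(pairs) + 1]] <<- t(combn(sort(idx), 2))
      }
      return(invisible())
    }
    sub <- v_cells[, idx, drop = FALSE]
    suppressWarnings(r <- cor(sub))
    r[is.na(r)] <- 0
    d <- 1 - r
    diag(d) <- 0
    hc <- hclust(as.dist(d), method = "ward.D2")
    grp <- cutree(hc, k = min(params$cluster_cut, length(idx)))
    for (g in unique(grp)) recurse(idx[grp == g])
  }
  recurse(seq_len(ncol(v_cells)))
  if (!length(pairs)) {
    matrix(integer(), ncol = 2)
  } else {
    do.call(rbind, pairs)
  }
}

#' One prediction repetition: iterative Ward clustering on a gene subsample
#'
#' Draws `ceiling(sampling_fraction * length(genes))` genes without replacement
#' from the current RNG state, then clusters the cells iteratively: the cell
#' set is split into `cluster_cut` groups by agglomerative hierarchical
#' clustering (ward.D2 linkage) on the Pearson correlation distance, and each
#' group is re-clustered (distances recomputed over the group's cells, same
#' gene subsample) until it holds at most `lineage_size_max` cells. Every
#' terminal group of 2 or more cells emits all its within-group pairs;
#' singletons emit nothing.
#'
#' @param m A normalized [expression_matrix()].
#' @param genes Character vector of selected gene ids (at least 2).
#' @param params A [prediction_params()] object (its `seed` is ignored here;
#'   the caller owns the RNG).
#' @param log1p Correlate log1p-transformed expression.
#' @return A two-column character matrix of unordered co-clustered cell pairs.
#' @export
one_prediction <- function(m, genes, params = prediction_params(),
                           log1p = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  genes <- intersect(genes, m$gene_ids)
  n_sub <- ceiling(params$sampling_fraction * length(genes))
  if (n_sub < 2) abort("gene subsample smaller than 2", class = "memlin_data_error")
  sub_genes <- if (n_sub < length(genes)) sample(genes, n_sub) else genes
  v <- as_dense(m, genes = sub_genes)
  if (log1p) v <- log1p(v)
  idx_pairs <- .iterative_split(v, params)
  matrix(m$cell_ids[idx_pairs], ncol = 2,
         dimnames = list(NULL, c("cell_a", "cell_b")))
}

#' Per-repetition RNG substream seeds
#'
#' Each prediction repetition runs under its own seed, derived once from
#' `params$seed`. Repetitions are therefore independent of execution order:
#' running them in any order (or in parallel) gives identical confidence
#' counts.
#'
#' @param params A [prediction_params()].
#' @return Integer vector of length `n_repetitions`.
#' @export
repetition_seeds <- function(params) {
  withr::with_seed(params$seed,
                   sample.int(.Machine$integer.max - 1L, params$n_repetitions))
}

#' Predict cell lineages: repeated iterative clustering to a confidence matrix
#'
#' Runs [one_prediction()] `n_repetitions` times, each on a fresh random gene
#' subsample, and counts for every cell pair the number of repetitions in which
#' it ended up in the same terminal cluster. Each repetition uses its own RNG
#' substream derived from `params$seed`, so the result is identical whatever
#' order the repetitions run in.
#'
#' @inheritParams one_prediction
#' @return A `confidence_matrix`: symmetric cell x cell integer counts in
#'   `[0, n_repetitions]`.
#' @export
predict_lineages <- function(m, genes, params = prediction_params(),
                             log1p = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  n <- length(m$cell_ids)
  counts <- matrix(0L, n, n, dimnames = list(m$cell_ids, m$cell_ids))
  rep_seeds <- repetition_seeds(params)
  for (r in seq_len(params$n_repetitions)) {
    prs <- withr::with_seed(rep_seeds[r],
                            one_prediction(m, genes, params, log1p = log1p))
    if (nrow(prs)) {
      i <- match(prs[, 1], m$cell_ids)
      j <- match(prs[, 2], m$cell_ids)
      k <- cbind(i, j)
      counts[k] <- counts[k] + 1L
      counts[k[, 2:1, drop = FALSE]] <- counts[k[, 2:1, drop = FALSE]] + 1L
    }
  }
  diag(counts) <- params$n_repetitions
  confidence_matrix(counts, params$n_repetitions, m$cell_ids)
}

#' Construct a confidence matrix
#'
#' @param counts Symmetric integer matrix of co-clustering counts.
#' @param n_repetitions Number of prediction repetitions the counts come from.
#' @param cell_ids Cell identifiers (rows/columns of `counts`).
#' @return A `confidence_matrix` object.
#' @export
confidence_matrix <- function(counts, n_repetitions, cell_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!isSymmetric(unname(counts))) {
    abort("confidence counts must be symmetric", class = "memlin_validation_error")
  }
  off <- counts[upper.tri(counts)]
  if (length(off) && (min(off) < 0 || max(off) > n_repetitions)) {
    abort("confidence counts must lie in [0, n_repetitions]",
          class = "memlin_validation_error")
  }
  dimnames(counts) <- list(cell_ids, cell_ids)
  structure(list(counts = counts, n_repetitions = as.integer(n_repetitions),
                 cell_ids = as.character(cell_ids)),
            class = "confidence_matrix")
}

#' @export
print.confidence_matrix <- function(x, ...) {
  np <- sum(x$counts[upper.tri(x$counts)] > 0)
  cat(sprintf("<confidence_matrix> %d cells, %d repetitions, %d pairs with confidence > 0\n",
              length(x$cell_ids), x$n_repetitions, np))
  invisible(x)
}

#' @describeIn confidence_matrix Long tibble of cell pairs with positive
#'   confidence (`cell_a`, `cell_b`, `confidence`).
#' @param x A `confidence_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.confidence_matrix <- function(x, ...) {
  ut <- upper.tri(x$counts)
  idx <- which(ut & x$counts > 0, arr.ind = TRUE)
  tibble(cell_a = x$cell_ids[idx[, 1]], cell_b = x$cell_ids[idx[, 2]],
         confidence = x$counts[idx]) |>
    arrange(dplyr::desc(.data$confidence), .data$cell_a, .data$cell_b)
}

#' Threshold a confidence matrix into lineages
#'
#' Cell pairs whose confidence is at or above `threshold` form the edges of a
#' graph; predicted lineages are its connected components of 2 or more cells.
#' Lineages can therefore grow beyond the terminal cluster size. Singletons
#' stay unassigned. Lineage ids are deterministic: numbered by the smallest
#' member cell index.
#'
#' @param cm A `confidence_matrix`.
#' @param threshold Integer in `[0, n_repetitions]`; pairs at or above it count
#'   as predicted related.
#' @return A `lineage_partition` tibble (`source = "predicted"`), with the
#'   threshold stored in attribute `threshold`.
#' @export
assign_lineages <- function(cm, threshold = 50) {
  stopifnot(inherits(cm, "confidence_matrix"))
  if (threshold > cm$n_repetitions) {
    warn(sprintf("threshold %d exceeds n_repetitions %d: no pair can qualify",
                 threshold, cm$n_repetitions))
  }
  n <- length(cm$cell_ids)
  adj <- cm$counts >= threshold
  diag(adj) <- FALSE
  # connected components via label propagation on the boolean adjacency
  comp <- seq_len(n)
  repeat {
    new_comp <- comp
    for (v in seq_len(n)) {
      nb <- which(adj[, v])
      if (length(nb)) new_comp[v] <- min(new_comp[v], min(comp[nb]))
    }
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  sizes <- table(comp)
  keep <- comp %in% as.integer(names(sizes)[sizes >= 2])
  roots <- sort(unique(comp[keep]))
  lab <- setNames(sprintf("L%d", seq_along(roots)), roots)
  out <- tibble(cell_id = cm$cell_ids[keep],
                lineage_id = unname(lab[as.character(comp[keep])]))
  out <- as_lineage_partition(out, source = "predicted")
  attr(out, "threshold") <- threshold
  out
}
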