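#' Sample skewness (third standardized moment)
#'
#' `m3 / m2^(3/2)` with central moments taken as plain averages, matching the
#' conventional definition used to split memory genes into quantitative
#' (skewness < 3) and qualitative (skewness >= 3) categories.
#'
#' @param x Numeric vector.
#' @return Skewness, or `NA` when the variance is zero.
#' @export
sample_skewness <- function(x) {
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mu)^3) / m2^1.5
}

# CV^2 of per-group mean expression: v is genes x cells (dense), groups a list
# of cell-index vectors. Degenerate genes (all group means zero) get 0.
.cv2_group_means <- function(v, groups) {
  k <- length(groups)
  ind <- matrix(0, ncol(v), k)
  for (g in seq_len(k)) ind[groups[[g]], g] <- 1 / length(groups[[g]])
  gm <- v %*% ind                      # genes x k matrix of group means
  mu <- rowMeans(gm)
  s2 <- rowSums((gm - mu)^2) / (k - 1)
  ifelse(mu > 0, s2 / mu^2, 0)
}

#' Call memory genes against a lineage annotation
#'
#' A memory gene keeps its expression level across divisions, so its
#' per-lineage mean expression varies more between lineages than between
#' random groups of cells. For each gene the statistic is the CV^2 of
#' per-lineage mean expression over lineages whose size falls in `size_range`;
#' it is compared one-sidedly to `n_null` size-matched random cell groupings
#' (disjoint groups drawn without replacement from the annotated cells,
#' matching the lineage-size multiset). The permutation p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_null)`, so with the default 20
#' replicates a gene is significant at 0.05 exactly when it beats every null.
#' Memory genes are then categorized by the skewness of their expression over
#' the lineage cells: quantitative below 3 (graded, broadly expressed levels),
#' qualitative at or above 3 (on/off across lineages).
#'
#' @param m A normalized [expression_matrix()].
#' @param lp A `lineage_partition` (ground truth or predicted).
#' @param size_range Two integers; only lineages with size in this range are
#'   used (typical choices: 2-5, or 3-5 for mESCs).
#' @param n_null Number of random size-matched groupings for the null.
#' @param alpha Significance level on the permutation p-value.
#' @param seed Integer seed for the null draws.
#' @return A tibble with one row per gene: `gene_id`, `cv2_lineage_means`,
#'   `p_value`, `is_memory`, `skewness`, `category` (factor
#'   quantitative/qualitative/none). Null statistics are kept in attribute
#'   `null_cv2` (genes x n_null), the cells used in `cells_used`.
#' @export
call_memory_genes <- function(m, lp, size_range = c(2, 5), n_null = 20,
                              alpha = 0.05, seed = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  lp <- as_tibble(lp)
  lp <- lp[lp$cell_id %in% m$cell_ids, ]
  sizes <- table(lp$lineage_id)
  used <- names(sizes)[sizes >= size_range[1] & sizes <= size_range[2]]
  if (length(used) < 2) {
    abort("need at least 2 lineages with size in size_range",
          class = "memlin_data_error")
  }
  pool <- lp$cell_id
  v <- as_dense(m, cells = pool)
  groups <- lapply(used, function(l) which(pool %in% lp$cell_id[lp$lineage_id == l]))
  observed <- .cv2_group_means(v, groups)
  size_multiset <- lengths(groups)

  null_cv2 <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      perm <- sample(length(pool))
      ends <- cumsum(size_multiset)
      starts <- c(1, head(ends, -1) + 1)
      rnd <- lapply(seq_along(size_multiset),
                    function(g) perm[starts[g]:ends[g]])
      .cv2_group_means(v, rnd)
    }, numeric(nrow(v)))
  })

  exceed <- rowSums(null_cv2 >= observed)
  p <- (1 + exceed) / (1 + n_null)
  lineage_cells <- pool[unlist(groups)]
  out <- tibble(gene_id = m$gene_ids,
                cv2_lineage_means = unname(observed),
                p_value = unname(p),
                is_memory = unname(p) <= alpha)
  attr(out, "null_cv2") <- null_cv2
  attr(out, "cells_used") <- lineage_cells
  attr(out, "lineages_used") <- used
  categorize_memory_genes(out, m)
}

#' Categorize memory genes as quantitative or qualitative
#'
#' Skewness of expression is computed over the cells belonging to the lineages
#' used for calling. Memory genes with skewness below 3 are quantitative,
#' at or above 3 qualitative; non-memory genes get `none`. A zero-variance
#' gene has undefined skewness and is forced quantitative with a warning (such
#' a gene cannot be a memory gene anyway).
#'
#' @param table Output of [call_memory_genes()] (or a tibble with `gene_id`
#'   and `is_memory` plus a `cells_used` attribute).
#' @param m The [expression_matrix()] the calls were made on.
#' @param cells Cells over which skewness is taken; defaults to the lineage
#'   cells recorded on `table`.
#' @param skew_cut Category boundary (default 3; skewness >= cut is
#'   qualitative).
#' @return `table` with `skewness` and `category` columns filled in.
#' @export
categorize_memory_genes <- function(table, m, cells = attr(table, "cells_used"),
                                    skew_cut = 3) {
  if (is.null(cells)) cells <- m$cell_ids
  v <- as_dense(m, cells = cells)
  sk <- apply(v, 1, sample_skewness)
  if (any(is.na(sk) & table$is_memory)) {
    warn("zero-variance memory gene: skewness undefined, forced quantitative")
  }
  category <- rep("none", nrow(table))
  category[table$is_memory] <-
    ifelse(!is.na(sk[table$is_memory]) & sk[table$is_memory] >= skew_cut,
           "qualitative", "quantitative")
  table$skewness <- unname(sk)
  table$category <- factor(category,
                           levels = c("quantitative", "qualitative", "none"))
  table
}

#' Lineage-mediated inflation of gene expression variation
#'
#' Fits, across genes, an ordinary least-squares line relating total CV^2
#' (variation across all lineage cells) to across-lineage CV^2 (variation of
#' per-lineage means), assuming within-lineage variation is independent of
#' cross-lineage effects. Mock lineages are then generated by permuting the
#' cell-to-lineage labels; the model predicts the total variation such control
#' sets would show, and the inflation is the percent difference of the median
#' per-gene standard deviation, real vs. control — reported over all genes and
#' over the top decile by mean expression ("highly expressed").
#'
#' @inheritParams call_memory_genes
#' @param n_perm Number of label permutations for the control.
#' @return A `variance_inflation` object: per-gene tibble (`gene_stats`),
#'   fitted `model` (intercept, slope), and an `inflation` tibble with
#'   `stratum` and `inflation_pct`. Use [glance()] for the one-row summary.
#' @export
variance_inflation <- function(m, lp, size_range = c(2, 5), n_perm = 20,
                               seed = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  lp <- as_tibble(lp)
  lp <- lp[lp$cell_id %in% m$cell_ids, ]
  sizes <- table(lp$lineage_id)
  used <- names(sizes)[sizes >= size_range[1] & sizes <= size_range[2]]
  if (length(used) < 2) {
    abort("need at least 2 lineages with size in size_range",
          class = "memlin_data_error")
  }
  lp <- lp[lp$lineage_id %in% used, ]
  cells <- lp$cell_id
  v <- as_dense(m, cells = cells)
  mu <- rowMeans(v)
  keep <- mu > 0
  if (sum(keep) < 10) abort("need at least 10 expressed genes",
                            class = "memlin_data_error")
  v <- v[keep, , drop = FALSE]
  mu <- mu[keep]
  n <- ncol(v)
  total_var <- rowSums((v - mu)^2) / (n - 1)
  total_cv2 <- total_var / mu^2
  groups <- lapply(used, function(l) which(cells %in% lp$cell_id[lp$lineage_id == l]))
  across_cv2 <- .cv2_group_means(v, groups)
  if (var(across_cv2) == 0) {
    abort("across-lineage CV^2 has zero variance; cannot fit",
          class = "memlin_numerical_error")
  }
  fit <- lm(total_cv2 ~ across_cv2)
  b <- coef(fit)
  real_sd <- sqrt(total_var)
  top <- mu >= quantile(mu, 0.9)

  ctrl <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      perm <- sample(n)
      rnd <- lapply(groups, function(g) perm[g])
      mock_across <- .cv2_group_means(v, rnd)
      ctrl_cv2 <- pmax(b[1] + b[2] * mock_across, 0)
      sqrt(ctrl_cv2) * mu        # control per-gene SD
    }, numeric(nrow(v)))
  })
  infl <- function(sel) {
    per_perm <- 100 * (median(real_sd[sel]) - apply(ctrl[sel, , drop = FALSE], 2, median)) /
      apply(ctrl[sel, , drop = FALSE], 2, median)
    mean(per_perm)
  }
  structure(
    list(
      gene_stats = tibble(gene_id = m$gene_ids[keep], mean_expr = unname(mu),
                          total_cv2 = unname(total_cv2),
                          across_lineage_cv2 = unname(across_cv2),
                          sd = unname(real_sd), top_decile = unname(top)),
      model = c(intercept = unname(b[1]), slope = unname(b[2])),
      inflation = tibble(stratum = c("all_genes", "top_decile_mean"),
                         inflation_pct = c(infl(rep(TRUE, length(mu))),
                                           infl(top))),
      n_perm = n_perm, lineages_used = used
    ),
    class = "variance_inflation"
  )
}

#' @export
print.variance_inflation <- function(x, ...) {
  cat(sprintf("<variance_inflation> %d lineages, slope %.3f\n",
              length(x$lineages_used), x$model["slope"]))
  print(x$inflation)
  invisible(x)
}

#' @describeIn variance_inflation One-row summary: model coefficients and the
#'   two inflation percentages.
#' @param x A `variance_inflation` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.variance_inflation <- function(x, ...) {
  tibble(intercept = x$model[["intercept"]], slope = x$model[["slope"]],
         inflation_pct_all = x$inflation$inflation_pct[1],
         inflation_pct_top_decile = x$inflation$inflation_pct[2],
         n_lineages = length(x$lineages_used), n_perm = x$n_perm)
}

#' Transcriptome similarity within lineages vs. random cell groups
#'
#' Pairwise Pearson correlation distances (over all genes) within each
#' multi-cell lineage, compared with `n_random` repeated draws of random cell
#' groups of the same sizes from the annotated cells.
#'
#' @inheritParams call_memory_genes
#' @param n_random Number of random size-matched replicates.
#' @return A tibble of pairwise distances with columns `set`
#'   (`"lineage"`/`"random"`), `replicate` (`NA` for lineages), `group_id`,
#'   `distance`; class `similarity_report`. [glance()] gives per-set medians
#'   and quartiles.
#' @export
similarity_report <- function(m, lp, n_random = 100, seed = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  lp <- as_tibble(lp)
  lp <- lp[lp$cell_id %in% m$cell_ids, ]
  sizes <- table(lp$lineage_id)
  multi <- names(sizes)[sizes >= 2]
  if (!length(multi)) abort("no lineage with 2 or more cells",
                            class = "memlin_data_error")
  pool <- lp$cell_id
  d <- correlation_distance(m, cells = pool)
  pair_dists <- function(ids) {
    prs <- t(combn(ids, 2))
    d[cbind(match(prs[, 1], pool), match(prs[, 2], pool))]
  }
  within <- purrr::map_dfr(multi, function(l) {
    ids <- lp$cell_id[lp$lineage_id == l]
    tibble(set = "lineage", replicate = NA_integer_, group_id = l,
           distance = pair_dists(ids))
  })
  size_multiset <- as.integer(sizes[multi])
  rand <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_random), function(r) {
      perm <- sample(pool)
      ends <- cumsum(size_multiset)
      starts <- c(1, head(ends, -1) + 1)
      purrr::map_dfr(seq_along(size_multiset), function(g) {
        tibble(set = "random", replicate = r,
               group_id = sprintf("R%d_%d", r, g),
               distance = pair_dists(perm[starts[g]:ends[g]]))
      })
    })
  })
  structure(bind_rows(within, rand),
            class = c("similarity_report", class(within)))
}

#' @describeIn similarity_report Medians and quartiles of the two distance
#'   distributions.
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.similarity_report <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$set) |>
    summarise(n_pairs = n(),
              q25 = quantile(.data$distance, 0.25),
              median = median(.data$distance),
              q75 = quantile(.data$distance, 0.75),
              .groups = "drop")
}
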