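# Long table of all unordered pairs of ground-truth-annotated cells with their
# confidence and truth co-lineage status. The universe for scoring: cells
# without ground truth are excluded entirely (not counted as negatives).
.pair_table <- function(cm, truth) {
  truth <- as_tibble(truth)
  cells <- intersect(cm$cell_ids, truth$cell_id)
  if (length(cells) < 2) abort("need at least 2 annotated cells",
                               class = "memlin_data_error")
  lin <- setNames(truth$lineage_id, truth$cell_id)[cells]
  idx <- t(combn(seq_along(cells), 2))
  tibble(
    cell_a = cells[idx[, 1]], cell_b = cells[idx[, 2]],
    confidence = cm$counts[cbind(match(cells[idx[, 1]], cm$cell_ids),
                                 match(cells[idx[, 2]], cm$cell_ids))],
    truth_pos = lin[idx[, 1]] == lin[idx[, 2]],
    lineage_a = unname(lin[idx[, 1]]), lineage_b = unname(lin[idx[, 2]])
  )
}

# Rank-based ROC area (Mann-Whitney with mid-ranks) of score vs. label.
.rank_auc <- function(score, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.confusion_trace <- function(pairs, thresholds) {
  purrr::map_dfr(thresholds, function(th) {
    pred <- pairs$confidence >= th
    tp <- sum(pred & pairs$truth_pos); fp <- sum(pred & !pairs$truth_pos)
    fn <- sum(!pred & pairs$truth_pos); tn <- sum(!pred & !pairs$truth_pos)
    tibble(threshold = th, tp = tp, fp = fp, fn = fn, tn = tn,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
  }) |>
    mutate(auc = .rank_auc(pairs$confidence, pairs$truth_pos))
}

#' Score predicted lineages against ground truth at the cell-pair level
#'
#' Every unordered pair of ground-truth-annotated cells is a case: positive
#' when both cells share a ground-truth lineage. At each confidence threshold
#' X, pairs with confidence >= X are predicted positive, giving TP/FP/FN/TN,
#' precision TP/(TP+FP), sensitivity TP/(TP+FN) and FPR FP/(FP+TN). The ROC
#' area (`auc`) is computed once from the confidence level as a ranking score.
#' Cells lacking ground truth are excluded from scoring entirely, since truth
#' annotations (e.g. barcodes) are typically partial and correct novel
#' predictions must not count as false positives.
#'
#' @param cm A `confidence_matrix` from [predict_lineages()].
#' @param truth Ground-truth `lineage_partition`.
#' @param thresholds Integer confidence thresholds to trace.
#' @return A `lineage_eval` tibble, one row per threshold.
#' @export
evaluate_lineages <- function(cm, truth,
                              thresholds = seq(0, cm$n_repetitions,
                                               by = max(1L, cm$n_repetitions %/% 10))) {
  pairs <- .pair_table(cm, truth)
  out <- .confusion_trace(pairs, thresholds)
  structure(out, class = c("lineage_eval", class(out)),
            n_pairs = nrow(pairs))
}

#' Label lineages or cell pairs as symmetric or asymmetric
#'
#' A lineage is symmetric when every member belongs to one cell type and
#' asymmetric when its members span two or more types; lineages with members
#' lacking a type annotation are labeled `unknown`. In pair mode each
#' within-lineage unordered pair is labeled: same type symmetric, different
#' types asymmetric.
#'
#' @param lp A `lineage_partition`.
#' @param ct Cell-type annotation tibble (`cell_id`, `cell_type`).
#' @param mode `"lineage"` or `"pair"`.
#' @return A tibble: `lineage_id`, `label` (lineage mode) or `cell_a`,
#'   `cell_b`, `lineage_id`, `label` (pair mode).
#' @export
classify_symmetry <- function(lp, ct, mode = c("lineage", "pair")) {
  mode <- match.arg(mode)
  lp <- as_tibble(lp)
  types <- setNames(ct$cell_type, ct$cell_id)
  if (mode == "lineage") {
    lp |>
      group_by(.data$lineage_id) |>
      summarise(label = {
        tt <- types[.data$cell_id]
        if (anyNA(tt)) "unknown"
        else if (length(unique(tt)) == 1) "symmetric" else "asymmetric"
      }, .groups = "drop")
  } else {
    purrr::map_dfr(split(lp$cell_id, lp$lineage_id), function(ids) {
      if (length(ids) < 2) return(tibble())
      prs <- t(combn(ids, 2))
      ta <- types[prs[, 1]]; tb <- types[prs[, 2]]
      tibble(cell_a = prs[, 1], cell_b = prs[, 2],
             label = dplyr::case_when(is.na(ta) | is.na(tb) ~ "unknown",
                                      ta == tb ~ "symmetric",
                                      TRUE ~ "asymmetric"))
    }, .id = "lineage_id")
  }
}

#' Pair-level evaluation stratified by symmetry or ground-truth lineage size
#'
#' With a cell-type annotation, every scored pair (over the entire prediction
#' matrix restricted to annotated cells) is placed in the `symmetric` stratum
#' when both cells share a cell type and `asymmetric` otherwise; pairs missing
#' a type are dropped. With `size_strata`, the stratum of size s holds the
#' pairs in which one or both cells belong to a ground-truth lineage of size
#' s. Metrics are as in [evaluate_lineages()], per stratum; empty strata are
#' reported with `NA` metrics.
#'
#' @inheritParams evaluate_lineages
#' @param ct Optional cell-type annotation (`cell_id`, `cell_type`).
#' @param size_strata Optional integer vector of ground-truth lineage sizes.
#' @return A `lineage_eval` tibble with a leading `stratum` column.
#' @export
stratified_evaluate <- function(cm, truth, ct = NULL, size_strata = NULL,
                                thresholds = seq(0, cm$n_repetitions,
                                                 by = max(1L, cm$n_repetitions %/% 10))) {
  pairs <- .pair_table(cm, truth)
  if (is.null(ct) == is.null(size_strata)) {
    abort("give exactly one of ct or size_strata", class = "memlin_parameter_error")
  }
  if (!is.null(ct)) {
    types <- setNames(ct$cell_type, ct$cell_id)
    ta <- types[pairs$cell_a]; tb <- types[pairs$cell_b]
    pairs$stratum <- dplyr::case_when(is.na(ta) | is.na(tb) ~ NA_character_,
                                      ta == tb ~ "symmetric",
                                      TRUE ~ "asymmetric")
    strata <- c("symmetric", "asymmetric")
  } else {
    sizes <- lineage_sizes(truth)
    sz <- setNames(sizes$size, sizes$lineage_id)
    strata <- as.character(size_strata)
  }
  out <- purrr::map_dfr(strata, function(s) {
    sub <- if (!is.null(ct)) {
      pairs[!is.na(pairs$stratum) & pairs$stratum == s, ]
    } else {
      sel <- sz[pairs$lineage_a] == as.integer(s) | sz[pairs$lineage_b] == as.integer(s)
      pairs[sel, ]
    }
    if (!nrow(sub)) {
      return(tibble(stratum = s, threshold = thresholds, tp = NA_integer_,
                    fp = NA_integer_, fn = NA_integer_, tn = NA_integer_,
                    precision = NA_real_, sensitivity = NA_real_,
                    fpr = NA_real_, auc = NA_real_))
    }
    mutate(.confusion_trace(sub, thresholds), stratum = s, .before = 1)
  })
  structure(out, class = c("lineage_eval", class(out)))
}

#' Count within-lineage cell pairs per cell-type combination
#'
#' For each unordered combination of cell types, counts the within-lineage
#' pairs whose members carry those types — the prevalence of each fate
#' combination among related cells.
#'
#' @param lp A `lineage_partition`.
#' @param ct Cell-type annotation (`cell_id`, `cell_type`).
#' @return A symmetric types x types integer matrix; the upper triangle plus
#'   diagonal holds each unordered combination once (mirrored below).
#' @export
pair_type_counts <- function(lp, ct) {
  prs <- classify_symmetry(lp, ct, mode = "pair")
  types <- sort(unique(ct$cell_type))
  out <- matrix(0L, length(types), length(types), dimnames = list(types, types))
  if (!nrow(prs)) return(out)
  tmap <- setNames(ct$cell_type, ct$cell_id)
  for (k in seq_len(nrow(prs))) {
    ta <- tmap[prs$cell_a[k]]; tb <- tmap[prs$cell_b[k]]
    if (is.na(ta) || is.na(tb)) next
    out[ta, tb] <- out[ta, tb] + 1L
    if (ta != tb) out[tb, ta] <- out[tb, ta] + 1L
  }
  out
}

#' @export
print.lineage_eval <- function(x, ...) {
  cat("<lineage_eval> pair-level precision/sensitivity/FPR trace\n")
  NextMethod()
}

#' @describeIn evaluate_lineages One-row summary of an evaluation: AUC and the
#'   metrics at the highest threshold with any predicted-positive pair.
#' @param x A `lineage_eval` tibble.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.lineage_eval <- function(x, ...) {
  tab <- as_tibble(x)
  with_pred <- tab[!is.na(tab$precision), ]
  at <- if (nrow(with_pred)) with_pred[which.max(with_pred$threshold), ] else tab[1, ]
  tibble(auc = tab$auc[1], best_threshold = at$threshold,
         precision = at$precision, sensitivity = at$sensitivity, fpr = at$fpr)
}
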