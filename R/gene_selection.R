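#' Per-gene mean, CV-squared and mean-corrected variability
#'
#' For each gene this computes the mean normalized expression, the squared
#' coefficient of variation (CV^2 = variance / mean^2) over cells, and a
#' mean-corrected variability: the residual of CV^2 to an ordinary
#' least-squares fit of CV^2 against mean expression across genes. Because the
#' CV^2-mean relation of count data is close to a power law, the fit is done in
#' log10-log10 space by default; a raw-space fit is available for comparison.
#' Percentile ranks of mean and variability (0-100, mean rank for ties) are
#' attached, computed over expressed genes only.
#'
#' Cells with zero total counts carry no information and are excluded. Genes
#' that are not detected in any cell get `NA` statistics; expressed genes with
#' zero variance are excluded from the fit and placed at the bottom of the
#' variability ranking.
#'
#' @param m A normalized [expression_matrix()] with at least 2 cells.
#' @param fit_space `"log"` (default) or `"raw"` scale for the CV^2-vs-mean fit.
#' @return A tibble with one row per gene: `gene_id`, `mean_expr`, `cv2`,
#'   `variability`, `mean_q`, `var_q`, `expressed`. The fitted intercept and
#'   slope are attached as attribute `fit`.
#' @export
gene_stats <- function(m, fit_space = c("log", "raw")) {
  stopifnot(inherits(m, "expression_matrix"))
  fit_space <- match.arg(fit_space)
  if (!m$normalized) {
    warn("gene_stats called on a raw matrix; normalize_depth() first is recommended")
  }
  totals <- cell_totals(m)
  keep <- names(totals)[totals > 0]
  if (length(keep) < 2) {
    abort("need at least 2 cells with nonzero counts", class = "memlin_data_error")
  }
  v <- as_dense(m, cells = keep)
  mu <- rowMeans(v)
  n <- ncol(v)
  vars <- rowSums((v - mu)^2) / (n - 1)
  cv2 <- ifelse(mu > 0, vars / mu^2, NA_real_)
  expressed <- mu > 0
  if (sum(expressed) < 2) {
    abort("fewer than 2 expressed genes; cannot fit CV^2 ~ mean",
          class = "memlin_data_error")
  }
  in_fit <- expressed & !is.na(cv2) & cv2 > 0
  if (sum(in_fit) < 2) {
    abort("fewer than 2 genes with positive variance; cannot fit CV^2 ~ mean",
          class = "memlin_data_error")
  }
  if (fit_space == "log") {
    x <- log10(mu[in_fit]); y <- log10(cv2[in_fit])
  } else {
    x <- mu[in_fit]; y <- cv2[in_fit]
  }
  fit <- lm(y ~ x)
  resid_fit <- unname(stats::residuals(fit))
  variability <- rep(NA_real_, length(mu))
  variability[in_fit] <- resid_fit
  # constant but expressed genes: no lineage signal, pinned below every residual
  variability[expressed & !in_fit] <- min(resid_fit) - 1

  pct_rank <- function(z) 100 * rank(z, ties.method = "average") / length(z)
  mean_q <- var_q <- rep(NA_real_, length(mu))
  mean_q[expressed] <- pct_rank(mu[expressed])
  # residuals are snapped to a grid far below the response scale before
  # ranking, so differences at floating-point noise level count as ties
  snap <- max(diff(range(y)), 1) * 1e-10
  var_q[in_fit] <- pct_rank(round(variability[in_fit] / snap) * snap)
  var_q[expressed & !in_fit] <- 0

  out <- tibble(
    gene_id = m$gene_ids, mean_expr = unname(mu), cv2 = unname(cv2),
    variability = unname(variability),
    mean_q = unname(mean_q), var_q = unname(var_q),
    expressed = unname(expressed)
  )
  attr(out, "fit") <- c(intercept = unname(coef(fit)[1]),
                        slope = unname(coef(fit)[2]))
  attr(out, "fit_space") <- fit_space
  out
}

#' Default mean/variability quantile thresholds for gene selection
#'
#' The disjunction keeps the 2% highest expressed genes, the 60% most variable
#' among the 10% highest expressed, and the 10% most variable among the 40%
#' highest expressed.
#'
#' @return A list of `(mean_q_min, var_q_min)` pairs.
#' @export
default_selection_rule <- function() {
  list(c(98, 0), c(90, 40), c(60, 90))
}

#' Select the memory-gene-enriched set used for lineage prediction
#'
#' A gene is selected when it satisfies ANY of the threshold pairs: mean
#' percentile at or above the first element AND variability percentile at or
#' above the second. The defaults strongly enrich genes whose expression level
#' is heritable within lineages.
#'
#' @param stats Output of [gene_stats()].
#' @param rule List of `(mean_q_min, var_q_min)` pairs (or a 2-column matrix);
#'   values in `[0, 100]`.
#' @return Character vector of selected gene ids, in input gene order.
#' @export
select_genes <- function(stats, rule = default_selection_rule()) {
  if (is.matrix(rule)) rule <- asplit(rule, 1)
  if (!length(rule)) abort("selection rule must be non-empty",
                           class = "memlin_parameter_error")
  ok <- vapply(rule, function(th) {
    if (length(th) != 2 || any(th < 0 | th > 100)) {
      abort("each threshold pair must be two values in [0, 100]",
            class = "memlin_parameter_error")
    }
    !is.na(stats$mean_q) & !is.na(stats$var_q) &
      stats$mean_q >= th[1] & stats$var_q >= th[2]
  }, logical(nrow(stats)))
  sel <- stats$gene_id[rowSums(ok) > 0]
  if (!length(sel)) {
    abort("no genes pass the selection rule; relax the thresholds",
          class = "memlin_data_error")
  }
  sel
}

#' Parse a `"98:0,90:40,60:90"` style threshold string
#'
#' @param text Comma-separated `mean:variability` quantile pairs.
#' @return A list of numeric pairs suitable for [select_genes()].
#' @export
parse_selection_rule <- function(text) {
  pairs <- strsplit(strsplit(text, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  lapply(pairs, function(p) as.numeric(p))
}
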