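make_lineage_data <- function(n_genes = 40, n_lineages = 6, size = 3,
                              sigma_lineage = 1, sigma_cell = 0.1, seed = 1) {
  withr::with_seed(seed, {
    lin <- rep(seq_len(n_lineages), each = size)
    mu <- rlnorm(n_genes, 3, 0.5)
    a <- matrix(rlnorm(n_genes * n_lineages, 0, sigma_lineage), n_genes)
    v <- mu * a[, lin] * matrix(rlnorm(n_genes * length(lin), 0, sigma_cell),
                                n_genes)
    dimnames(v) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("c%03d", seq_along(lin)))
    list(m = expression_matrix(v, normalized = TRUE),
         lp = as_lineage_partition(setNames(sprintf("T%d", lin), colnames(v))))
  })
}

test_that("cv2 of lineage means matches direct recomputation and planted genes are called", {
  d <- make_lineage_data(seed = 2)
  tab <- call_memory_genes(d$m, d$lp, size_range = c(2, 5), seed = 3)
  # direct recomputation for a few genes
  v <- as_dense(d$m)
  lin <- setNames(d$lp$lineage_id, d$lp$cell_id)
  for (g in c(1, 17, 40)) {
    means <- tapply(v[g, d$lp$cell_id], lin[d$lp$cell_id], mean)
    expect_equal(tab$cv2_lineage_means[g], var(means) / mean(means)^2,
                 tolerance = 1e-12)
  }
  # strong lineage structure: essentially all genes beat all 20 nulls
  expect_equal(min(tab$p_value), 1 / 21, tolerance = 1e-12)
  expect_gt(mean(tab$is_memory), 0.9)
})

test_that("a constant gene ties with its nulls and is never a memory gene", {
  d <- make_lineage_data(n_genes = 10, seed = 4)
  v <- as_dense(d$m)
  v[1, ] <- 7                       # constant
  v[2, ] <- 0                       # undetected
  m <- expression_matrix(v, normalized = TRUE)
  tab <- call_memory_genes(m, d$lp, seed = 5)
  expect_equal(tab$p_value[1], 1)
  expect_false(tab$is_memory[1])
  expect_equal(tab$p_value[2], 1)
  expect_identical(as.character(tab$category[1:2]), c("none", "none"))
})

test_that("permuting lineage labels destroys memory calls at about the alpha rate", {
  d <- make_lineage_data(n_genes = 200, n_lineages = 8, size = 3,
                         sigma_lineage = 1, seed = 6)
  perm_lp <- withr::with_seed(7, as_lineage_partition(
    setNames(sample(d$lp$lineage_id), d$lp$cell_id)))
  tab <- call_memory_genes(d$m, perm_lp, seed = 8)
  # under exchangeability p <= 0.05 happens with prob 1/21
  expect_lt(mean(tab$is_memory), 0.05 + 0.04)
})

test_that("memory calls are invariant to lineage relabeling and cell order", {
  d <- make_lineage_data(seed = 9)
  tab1 <- call_memory_genes(d$m, d$lp, seed = 10)
  relab <- d$lp
  relab$lineage_id <- paste0("XX_", relab$lineage_id)
  tab2 <- call_memory_genes(d$m, as_lineage_partition(relab), seed = 10)
  expect_equal(tab1$p_value, tab2$p_value)
  shuffled <- withr::with_seed(11, d$lp[sample(nrow(d$lp)), ])
  tab3 <- call_memory_genes(d$m, as_lineage_partition(shuffled), seed = 10)
  expect_equal(tab1$cv2_lineage_means, tab3$cv2_lineage_means)
})

test_that("skewness follows the Bernoulli closed form and the cut is at exactly 3", {
  # on in 1% of cells: skewness ~ (1 - 2p) / sqrt(p (1 - p)) ~ 9.85
  x <- c(rep(1, 2), rep(0, 198))
  p <- 2 / 200
  expect_equal(sample_skewness(x), (1 - 2 * p) / sqrt(p * (1 - p)),
               tolerance = 1e-12)
  # symmetric distribution -> skewness 0
  expect_equal(sample_skewness(c(1, 2, 3, 4, 5)), 0)
  # category boundary: skewness exactly 3 is qualitative
  tab <- tibble::tibble(gene_id = c("g1", "g2"), is_memory = c(TRUE, TRUE))
  vals <- c(10, 1, 1)                      # skewness sqrt(2)/... compute below
  m <- expression_matrix(
    matrix(c(vals, 1, 2, 3), nrow = 2, byrow = TRUE,
           dimnames = list(c("g1", "g2"), c("c1", "c2", "c3"))),
    normalized = TRUE)
  attr(tab, "cells_used") <- c("c1", "c2", "c3")
  out <- categorize_memory_genes(tab, m)
  # {10,1,1} has skewness sqrt(2)/sqrt(2)... verify against direct formula
  expect_equal(out$skewness[1], sample_skewness(c(10, 1, 1)))
  expect_identical(as.character(out$category),
                   ifelse(out$skewness >= 3, "qualitative", "quantitative"))
  # boundary inclusive on the qualitative side: a skew_cut at the observed
  # skewness still labels the gene qualitative
  out2 <- categorize_memory_genes(tab, m, skew_cut = out$skewness[1])
  expect_identical(as.character(out2$category[1]), "qualitative")
})

test_that("categories are exclusive, exhaustive over memory genes, and planted classes recovered", {
  ds <- .default_sim()
  m <- normalized_quietly(ds$counts)
  tab <- call_memory_genes(m, ds$truth_lineages, size_range = c(2, 5), seed = 12)
  expect_equal(sum(tab$category != "none"), sum(tab$is_memory))
  expect_equal(sum(tab$category == "quantitative") +
                 sum(tab$category == "qualitative"), sum(tab$is_memory))
  truth <- ds$truth_memory
  for (cl in c("quantitative", "qualitative")) {
    planted <- truth$gene_id[truth$category == cl]
    called <- tab[match(planted, tab$gene_id), ]
    hit <- called$category[called$is_memory]
    expect_gt(mean(hit == cl), 0.6)  # full-scale recovery asserted in test-acceptance
  }
})

test_that("variance inflation is near zero for random labels and grows with planted effects", {
  base <- make_lineage_data(n_genes = 150, n_lineages = 10, size = 4,
                            sigma_lineage = 0, sigma_cell = 0.4, seed = 13)
  null_res <- variance_inflation(base$m, base$lp, size_range = c(2, 6),
                                 n_perm = 20, seed = 14)
  infl_null <- null_res$inflation$inflation_pct[1]
  expect_lt(abs(infl_null), 5)

  small <- make_lineage_data(n_genes = 150, n_lineages = 10, size = 4,
                             sigma_lineage = 0.4, sigma_cell = 0.4, seed = 13)
  big <- make_lineage_data(n_genes = 150, n_lineages = 10, size = 4,
                           sigma_lineage = 0.8, sigma_cell = 0.4, seed = 13)
  i_small <- variance_inflation(small$m, small$lp, size_range = c(2, 6),
                                n_perm = 20, seed = 14)$inflation$inflation_pct[1]
  i_big <- variance_inflation(big$m, big$lp, size_range = c(2, 6),
                              n_perm = 20, seed = 14)$inflation$inflation_pct[1]
  expect_gt(i_small, infl_null)
  expect_gt(i_big, i_small)
  g <- glance(variance_inflation(big$m, big$lp, size_range = c(2, 6),
                                 n_perm = 5, seed = 1))
  expect_named(g, c("intercept", "slope", "inflation_pct_all",
                    "inflation_pct_top_decile", "n_lineages", "n_perm"))
})

test_that("similarity report separates lineages of duplicated profiles from random groups", {
  quads <- make_grouped_cells(c(3, 3, 3), seed = 15, jitter = 0)
  lp <- as_lineage_partition(setNames(sprintf("T%d", quads$group),
                                      quads$m$cell_ids))
  rep_ <- similarity_report(quads$m, lp, n_random = 20, seed = 16)
  g <- glance(rep_)
  expect_equal(g$median[g$set == "lineage"], 0, tolerance = 1e-12)
  expect_gt(g$median[g$set == "random"], 0)
  # n_random = 1 boundary
  one <- similarity_report(quads$m, lp, n_random = 1, seed = 17)
  expect_equal(max(one$replicate, na.rm = TRUE), 1)
})

test_that("with permuted labels the two distance distributions are indistinguishable", {
  d <- make_lineage_data(n_genes = 30, n_lineages = 8, size = 3,
                         sigma_lineage = 0, sigma_cell = 0.3, seed = 18)
  n_pass <- 0
  for (s in 1:10) {
    rep_ <- similarity_report(d$m, d$lp, n_random = 30, seed = s)
    pv <- stats::wilcox.test(rep_$distance[rep_$set == "lineage"],
                             rep_$distance[rep_$set == "random"])$p.value
    n_pass <- n_pass + (pv > 0.01)
  }
  expect_gte(n_pass, 9)
})
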