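cm_from_pairs <- function(cells, pairs, scores, n_rep = 100) {
  counts <- matrix(0L, length(cells), length(cells),
                   dimnames = list(cells, cells))
  for (k in seq_along(scores)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    counts[a, b] <- counts[b, a] <- as.integer(scores[k])
  }
  diag(counts) <- as.integer(n_rep)
  confidence_matrix(counts, n_rep, cells)
}

test_that("hand-computable confusion counts: TP=1 FP=1 FN=0 TN=4", {
  cells <- c("A", "B", "C", "D")
  truth <- as_lineage_partition(c(A = "T1", B = "T1", C = "T2", D = "T3"))
  cm <- cm_from_pairs(cells, list(c("A", "B"), c("A", "C")), c(80, 60))
  ev <- evaluate_lineages(cm, truth, thresholds = 50)
  expect_equal(ev$tp, 1); expect_equal(ev$fp, 1)
  expect_equal(ev$fn, 0); expect_equal(ev$tn, 4)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$fpr, 0.2)
})

test_that("perfect prediction scores precision 1, sensitivity 1, FPR 0, AUC 1", {
  cells <- c("A", "B", "C", "D")
  truth <- as_lineage_partition(c(A = "T1", B = "T1", C = "T2", D = "T2"))
  cm <- cm_from_pairs(cells, list(c("A", "B"), c("C", "D")), c(90, 90))
  ev <- evaluate_lineages(cm, truth, thresholds = 50)
  expect_equal(c(ev$precision, ev$sensitivity, ev$fpr), c(1, 1, 0))
  expect_equal(ev$auc, 1)
})

test_that("one positive ranked above all negatives gives AUC 1", {
  cells <- c("A", "B", "C", "D")
  truth <- as_lineage_partition(c(A = "T1", B = "T1", C = "T2", D = "T3"))
  cm <- cm_from_pairs(cells, list(c("A", "B"), c("C", "D"), c("A", "C"),
                                  c("A", "D"), c("B", "C"), c("B", "D")),
                      c(90, 10, 10, 10, 10, 10))
  ev <- evaluate_lineages(cm, truth, thresholds = 50)
  expect_equal(ev$auc, 1.0)
})

test_that("evaluate matches the exhaustive pair-enumeration oracle on random matrices", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(10:50, 1)
      cells <- sprintf("c%02d", seq_len(n))
      counts <- matrix(0L, n, n, dimnames = list(cells, cells))
      up <- upper.tri(counts)
      counts[up] <- sample(0:100, sum(up), replace = TRUE)
      counts <- pmax(counts, t(counts))
      diag(counts) <- 100L
      cm <- confidence_matrix(counts, 100, cells)
      # truth: ~15 lineages, some cells unannotated
      ann <- sample(cells, round(0.8 * n))
      truth <- as_lineage_partition(
        setNames(sprintf("T%d", sample(15, length(ann), replace = TRUE)), ann))
    })
    for (th in c(0, 30, 70, 101)) {
      got <- evaluate_lineages(cm, truth, thresholds = th)
      want <- oracle_pair_metrics(cm, truth, th)
      expect_equal(got$tp, want$tp); expect_equal(got$fp, want$fp)
      expect_equal(got$fn, want$fn); expect_equal(got$tn, want$tn)
      expect_equal(got$precision, want$precision)
      expect_equal(got$sensitivity, want$sensitivity)
      expect_equal(got$fpr, want$fpr)
      expect_equal(got$auc, want$auc, tolerance = 1e-12)
    }
  }
})

test_that("counts conserve and traces are monotone over thresholds", {
  ds <- .default_sim()
  m <- normalized_quietly(ds$counts)
  genes <- select_genes(gene_stats(m))
  cm <- predict_lineages(m, genes, prediction_params(n_repetitions = 25, seed = 3))
  ev <- evaluate_lineages(cm, ds$truth_lineages, thresholds = seq(0, 25, 5))
  n_truth_pairs <- ev$tp[1] + ev$fn[1]
  expect_true(all(ev$tp + ev$fn == n_truth_pairs))
  expect_true(all(ev$tp + ev$fp + ev$fn + ev$tn ==
                    choose(length(ds$truth_lineages$cell_id), 2)))
  expect_true(all(diff(ev$sensitivity) <= 0))
  expect_true(all(diff(ev$fp) <= 0))
})

test_that("symmetry labels follow the cell types of lineage members", {
  lp <- as_lineage_partition(c(c1 = "T1", c2 = "T1", c3 = "T1",
                               c4 = "T2", c5 = "T2"))
  ct <- tibble::tibble(cell_id = c("c1", "c2", "c3", "c4", "c5"),
                       cell_type = c("A", "B", "A", "A", "A"))
  lab <- classify_symmetry(lp, ct, mode = "lineage")
  expect_equal(lab$label[lab$lineage_id == "T1"], "asymmetric")
  expect_equal(lab$label[lab$lineage_id == "T2"], "symmetric")
  prs <- classify_symmetry(lp, ct, mode = "pair")
  t1 <- prs[prs$lineage_id == "T1", ]
  expect_equal(t1$label[t1$cell_a == "c1" & t1$cell_b == "c3"], "symmetric")
  expect_equal(sort(t1$label), c("asymmetric", "asymmetric", "symmetric"))
  # missing annotation -> unknown
  ct2 <- ct[-1, ]
  lab2 <- classify_symmetry(lp, ct2, mode = "lineage")
  expect_equal(lab2$label[lab2$lineage_id == "T1"], "unknown")
})

test_that("stratified evaluation conserves truth pairs per stratum", {
  ds <- simulate_dataset(simulation_config(
    n_lineages = 15, n_genes = 300, n_celltypes = 2, frac_asymmetric = 0.4,
    n_marker_genes = 20, seed = 21))
  m <- normalized_quietly(ds$counts)
  genes <- select_genes(gene_stats(m))
  cm <- predict_lineages(m, genes, prediction_params(n_repetitions = 10, seed = 4))
  ev <- stratified_evaluate(cm, ds$truth_lineages, ct = ds$truth_celltypes,
                            thresholds = c(0, 5))
  # per-stratum truth pairs: direct enumeration over annotated pairs
  lin <- setNames(ds$truth_lineages$lineage_id, ds$truth_lineages$cell_id)
  typ <- setNames(ds$truth_celltypes$cell_type, ds$truth_celltypes$cell_id)
  cells <- ds$truth_lineages$cell_id
  combos <- t(combn(cells, 2))
  sym <- typ[combos[, 1]] == typ[combos[, 2]]
  pos <- lin[combos[, 1]] == lin[combos[, 2]]
  for (s in c("symmetric", "asymmetric")) {
    want <- sum(pos & (sym == (s == "symmetric")))
    sub <- ev[ev$stratum == s, ]
    expect_true(all(sub$tp + sub$fn == want))
  }
})

test_that("single-type data leaves the asymmetric stratum empty and matches global eval", {
  ds <- .default_sim()
  m <- normalized_quietly(ds$counts)
  ct <- tibble::tibble(cell_id = m$cell_ids, cell_type = "only")
  genes <- select_genes(gene_stats(m))
  cm <- predict_lineages(m, genes, prediction_params(n_repetitions = 5, seed = 6))
  ev <- stratified_evaluate(cm, ds$truth_lineages, ct = ct, thresholds = c(0, 3))
  asym <- ev[ev$stratum == "asymmetric", ]
  expect_true(all(is.na(asym$precision)))
  sym <- ev[ev$stratum == "symmetric", ]
  glob <- evaluate_lineages(cm, ds$truth_lineages, thresholds = c(0, 3))
  expect_equal(sym$tp, glob$tp)
  expect_equal(sym$tn, glob$tn)
})

test_that("size strata select pairs touching lineages of that size", {
  # truth with only 3-cell lineages: size-2 stratum is empty
  lp <- as_lineage_partition(c(a = "T1", b = "T1", c = "T1",
                               d = "T2", e = "T2", f = "T2"))
  cm <- cm_from_pairs(c("a", "b", "c", "d", "e", "f"),
                      list(c("a", "b")), 90)
  ev <- stratified_evaluate(cm, lp, size_strata = c(2, 3), thresholds = 50)
  expect_true(is.na(ev$tp[ev$stratum == "2"]))
  s3 <- ev[ev$stratum == "3", ]
  expect_equal(s3$tp + s3$fp + s3$fn + s3$tn, choose(6, 2))
})

test_that("pair type counts enumerate within-lineage type combinations", {
  lp <- as_lineage_partition(c(c1 = "T1", c2 = "T1"))
  ct <- tibble::tibble(cell_id = c("c1", "c2"), cell_type = c("A", "B"))
  cnt <- pair_type_counts(lp, ct)
  expect_equal(cnt["A", "B"], 1L)
  expect_equal(sum(cnt[upper.tri(cnt, diag = TRUE)]), 1L)

  lp2 <- as_lineage_partition(c(c1 = "T1", c2 = "T1", c3 = "T1",
                                c4 = "T2", c5 = "T2"))
  ct2 <- tibble::tibble(cell_id = paste0("c", 1:5),
                        cell_type = c("A", "A", "B", "B", "B"))
  cnt2 <- pair_type_counts(lp2, ct2)
  expect_equal(cnt2["A", "A"], 1L)
  expect_equal(cnt2["A", "B"], 2L)
  expect_equal(cnt2["B", "B"], 1L)
  # conservation: total pairs = sum over lineages of choose(size, 2)
  expect_equal(sum(cnt2[upper.tri(cnt2, diag = TRUE)]),
               sum(choose(lineage_sizes(lp2)$size, 2)))
})
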