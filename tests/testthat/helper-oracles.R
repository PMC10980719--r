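# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::hclust): naive O(n^3) agglomeration,
# exhaustive pair enumeration, closed forms.

# Naive ward.D2 agglomeration on a distance matrix; returns cluster
# memberships after stopping at k clusters. Lance-Williams update on squared
# distances; ties broken on the lexicographically smallest index pair.
oracle_ward_cut <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- d
  diag(D) <- Inf
  while (length(clusters) > k) {
    m <- length(clusters)
    best <- c(NA, NA); best_val <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (D[i, j] < best_val - 1e-12) { best_val <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    newd <- sapply(seq_len(m), function(l) {
      if (l == i || l == j) return(Inf)
      nl <- sizes[l]
      sqrt(((ni + nl) * D[i, l]^2 + (nj + nl) * D[j, l]^2 - nl * D[i, j]^2) /
             (ni + nj + nl))
    })
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], Inf))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], ni + nj)
    D <- D2
  }
  memb <- integer(n)
  for (g in seq_along(clusters)) memb[clusters[[g]]] <- g
  memb
}

# Brute-force recursive Ward splitter: same contract as one_prediction with
# sampling_fraction = 1, but built on oracle_ward_cut.
oracle_recursive_split <- function(v, cluster_cut = 2, size_max = 3) {
  pairs <- list()
  recurse <- function(idx) {
    if (length(idx) <= size_max) {
      if (length(idx) >= 2) {
        pairs[[length(pairs) + 1]] <<- t(combn(sort(idx), 2))
      }
      return(invisible())
    }
    sub <- v[, idx, drop = FALSE]
    suppressWarnings(r <- cor(sub))
    r[is.na(r)] <- 0
    d <- 1 - r; diag(d) <- 0
    memb <- oracle_ward_cut(d, min(cluster_cut, length(idx)))
    for (g in unique(memb)) recurse(idx[memb == g])
  }
  recurse(seq_len(ncol(v)))
  if (!length(pairs)) matrix(integer(), ncol = 2) else do.call(rbind, pairs)
}

pairs_key <- function(p) {
  if (!nrow(p)) return(character())
  sort(paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]), sep = "|"))
}

# Exhaustive O(n^2) pair-level confusion + AUC by explicit win counting.
oracle_pair_metrics <- function(cm, truth, threshold) {
  truth <- as.data.frame(truth)
  cells <- intersect(cm$cell_ids, truth$cell_id)
  lin <- setNames(truth$lineage_id, truth$cell_id)
  tp <- fp <- fn <- tn <- 0
  scores <- c(); labels <- c()
  for (a in seq_along(cells)) for (b in seq_len(a - 1)) {
    ca <- cells[a]; cb <- cells[b]
    conf <- cm$counts[ca, cb]
    pos <- lin[ca] == lin[cb]
    pred <- conf >= threshold
    if (pred && pos) tp <- tp + 1
    if (pred && !pos) fp <- fp + 1
    if (!pred && pos) fn <- fn + 1
    if (!pred && !pos) tn <- tn + 1
    scores <- c(scores, conf); labels <- c(labels, pos)
  }
  pos_s <- scores[labels]; neg_s <- scores[!labels]
  auc <- if (length(pos_s) && length(neg_s)) {
    wins <- 0
    for (p in pos_s) for (q in neg_s) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
    wins / (length(pos_s) * length(neg_s))
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       auc = auc)
}
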