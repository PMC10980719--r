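# Small in-code fixtures.

# Random count matrix with no structure.
make_counts <- function(n_genes = 20, n_cells = 6, seed = 1, depth = 200) {
  withr::with_seed(seed, {
    v <- matrix(rpois(n_genes * n_cells, depth / n_genes), n_genes, n_cells)
    dimnames(v) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("c%02d", seq_len(n_cells)))
    expression_matrix(v)
  })
}

# Cells planted in tight groups: each group shares a profile, plus small
# jitter so all distances are distinct (no Ward ties).
make_grouped_cells <- function(group_sizes, n_genes = 30, seed = 1,
                               jitter = 0.01) {
  withr::with_seed(seed, {
    n_cells <- sum(group_sizes)
    centers <- matrix(rlnorm(n_genes * length(group_sizes), 3, 1),
                      n_genes, length(group_sizes))
    grp <- rep(seq_along(group_sizes), group_sizes)
    v <- centers[, grp] * matrix(rlnorm(n_genes * n_cells, 0, jitter),
                                 n_genes, n_cells)
    dimnames(v) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("c%02d", seq_len(n_cells)))
    list(m = expression_matrix(v), group = grp)
  })
}

normalized_quietly <- function(m, depth = 40000) {
  suppressWarnings(normalize_depth(m, target_depth = depth))
}

# One small simulated dataset shared by several test files (cached).
.default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(simulation_config(
        n_lineages = 20, n_genes = 500, seed = 99))
    }
    cache
  }
})
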