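#' Configuration of the lineage-structured count simulator
#'
#' The generator plants three gene classes over a set of small lineages
#' (clones of 2-5 cells by default): quantitative memory genes carry a
#' lineage-specific log-normal level multiplier with small within-lineage
#' noise; qualitative memory genes are switched on in a small fraction of
#' lineages and off elsewhere (giving strongly right-skewed expression);
#' non-memory genes fluctuate independently per cell. Rates are scaled to a
#' target sequencing depth with log-normal library-size variation and read out
#' through Poisson sampling (a Poisson-log-normal mixture, giving realistic
#' overdispersion). Optional cell-type programs multiply marker-gene rates by
#' a type factor, and a fraction of lineages can span two types (asymmetric
#' lineages).
#'
#' @param n_lineages Number of lineages.
#' @param lineage_size_dist Integer vector of sizes to draw uniformly from.
#' @param n_genes Number of genes.
#' @param frac_quant_memory,frac_qual_memory Fractions of genes planted as
#'   quantitative / qualitative memory genes (defaults echo the roughly 20%
#'   memory-gene fraction seen in real data, split ~60/40).
#' @param base_mean_logdist `c(meanlog, sdlog)` of the log-normal base gene
#'   means.
#' @param sigma_lineage Between-lineage log-scale SD of the quantitative
#'   memory effect.
#' @param sigma_cell Per-cell log-scale noise SD of non-memory genes.
#' @param sigma_cell_memory Residual per-cell noise SD of memory genes (small:
#'   memory means the level persists within the lineage).
#' @param qual_on_fraction Probability a qualitative gene is active in a given
#'   lineage.
#' @param memory_mean_logshift Log-scale shift added to the base mean of
#'   memory genes: detectable expression memory is a property of
#'   moderately-to-highly expressed genes (sampling noise swamps it in lowly
#'   expressed ones).
#' @param qual_on_level Extra rate multiplier of an active qualitative gene:
#'   on/off bimodal genes are strongly expressed in their ON state.
#' @param depth Expected reads per cell.
#' @param sigma_libsize Log-scale SD of cell library sizes.
#' @param n_celltypes Number of cell types (1 = no type structure).
#' @param frac_asymmetric Fraction of lineages spanning two cell types.
#' @param n_marker_genes Marker genes per cell type (taken from the
#'   non-memory pool).
#' @param marker_strength Rate multiplier of a marker gene in its own type.
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_lineages = 57, lineage_size_dist = 2:5,
                              n_genes = 2000, frac_quant_memory = 0.12,
                              frac_qual_memory = 0.08,
                              base_mean_logdist = c(meanlog = 0, sdlog = 1),
                              sigma_lineage = 0.4, sigma_cell = 0.6,
                              sigma_cell_memory = 0.3, qual_on_fraction = 0.05,
                              memory_mean_logshift = 1.8, qual_on_level = 3,
                              depth = 8000, sigma_libsize = 0.25,
                              n_celltypes = 1, frac_asymmetric = 0,
                              n_marker_genes = 50, marker_strength = 5,
                              seed = 1) {
  cfg <- as.list(environment())
  if (cfg$frac_quant_memory + cfg$frac_qual_memory > 1) {
    abort("memory gene fractions exceed 1", class = "memlin_parameter_error")
  }
  if (any(c(cfg$sigma_lineage, cfg$sigma_cell, cfg$sigma_cell_memory,
            cfg$sigma_libsize) < 0) || cfg$depth <= 0) {
    abort("SDs must be >= 0 and depth > 0", class = "memlin_parameter_error")
  }
  n_mem <- round((cfg$frac_quant_memory + cfg$frac_qual_memory) * cfg$n_genes)
  if (cfg$n_celltypes > 1 &&
      cfg$n_celltypes * cfg$n_marker_genes > cfg$n_genes - n_mem) {
    abort("marker genes exceed the non-memory gene pool",
          class = "memlin_parameter_error")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a lineage-annotated scRNA-seq dataset
#'
#' @param config A [simulation_config()].
#' @return A `simulated_dataset` list: `counts` (raw [expression_matrix()]),
#'   `truth_lineages` (`lineage_partition`), `truth_celltypes` (tibble or
#'   `NULL`), `truth_memory` (tibble `gene_id`, `category`), and the `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  sizes <- cfg$lineage_size_dist[sample.int(length(cfg$lineage_size_dist),
                                            cfg$n_lineages, replace = TRUE)]
  n_cells <- sum(sizes)
  lineage_of <- rep(seq_len(cfg$n_lineages), sizes)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  lineage_ids <- sprintf("T%03d", seq_len(cfg$n_lineages))
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))

  n_quant <- round(cfg$frac_quant_memory * cfg$n_genes)
  n_qual <- round(cfg$frac_qual_memory * cfg$n_genes)
  role <- rep("none", cfg$n_genes)
  mem_idx <- sample(cfg$n_genes, n_quant + n_qual)
  role[mem_idx[seq_len(n_quant)]] <- "quantitative"
  if (n_qual > 0) role[mem_idx[n_quant + seq_len(n_qual)]] <- "qualitative"

  mu <- rlnorm(cfg$n_genes, cfg$base_mean_logdist[[1]], cfg$base_mean_logdist[[2]])
  mu[role != "none"] <- mu[role != "none"] * exp(cfg$memory_mean_logshift)
  rate <- matrix(0, cfg$n_genes, n_cells)

  is_quant <- role == "quantitative"
  is_qual <- role == "qualitative"
  is_none <- role == "none"
  # lineage-level effects
  if (any(is_quant)) {
    a <- matrix(rlnorm(sum(is_quant) * cfg$n_lineages, 0, cfg$sigma_lineage),
                sum(is_quant), cfg$n_lineages)
    eps <- matrix(rlnorm(sum(is_quant) * n_cells, 0, cfg$sigma_cell_memory),
                  sum(is_quant), n_cells)
    rate[is_quant, ] <- mu[is_quant] * a[, lineage_of] * eps
  }
  if (any(is_qual)) {
    on <- matrix(runif(sum(is_qual) * cfg$n_lineages) < cfg$qual_on_fraction,
                 sum(is_qual), cfg$n_lineages)
    eps <- matrix(rlnorm(sum(is_qual) * n_cells, 0, cfg$sigma_cell_memory),
                  sum(is_qual), n_cells)
    rate[is_qual, ] <- mu[is_qual] * cfg$qual_on_level * on[, lineage_of] * eps
  }
  if (any(is_none)) {
    eps <- matrix(rlnorm(sum(is_none) * n_cells, 0, cfg$sigma_cell),
                  sum(is_none), n_cells)
    rate[is_none, ] <- mu[is_none] * eps
  }

  # cell types: whole lineages get a type; asymmetric lineages span two
  celltypes <- NULL
  if (cfg$n_celltypes > 1) {
    type_names <- sprintf("type%d", seq_len(cfg$n_celltypes))
    lin_type <- sample(cfg$n_celltypes, cfg$n_lineages, replace = TRUE)
    cell_type <- lin_type[lineage_of]
    n_asym <- round(cfg$frac_asymmetric * cfg$n_lineages)
    if (n_asym > 0) {
      asym <- sample(which(sizes >= 2), min(n_asym, sum(sizes >= 2)))
      for (l in asym) {
        members <- which(lineage_of == l)
        other <- sample(setdiff(seq_len(cfg$n_celltypes), lin_type[l]), 1)
        flip <- members[seq_len(ceiling(length(members) / 2))]
        cell_type[flip] <- other
      }
    }
    marker_pool <- which(is_none)
    markers <- split(sample(marker_pool, cfg$n_celltypes * cfg$n_marker_genes),
                     rep(seq_len(cfg$n_celltypes), each = cfg$n_marker_genes))
    for (t in seq_len(cfg$n_celltypes)) {
      cells_t <- which(cell_type == t)
      if (length(cells_t)) {
        rate[markers[[t]], cells_t] <- rate[markers[[t]], cells_t] * cfg$marker_strength
      }
    }
    celltypes <- tibble(cell_id = cell_ids, cell_type = type_names[cell_type])
  }

  lib <- cfg$depth * rlnorm(n_cells, 0, cfg$sigma_libsize)
  col_rate <- colSums(rate)
  scale <- ifelse(col_rate > 0, lib / col_rate, 0)
  lambda <- sweep(rate, 2, scale, `*`)
  counts <- matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  dimnames(counts) <- list(gene_ids, cell_ids)

  structure(list(
    counts = expression_matrix(counts),
    truth_lineages = as_lineage_partition(
      tibble(cell_id = cell_ids, lineage_id = lineage_ids[lineage_of]),
      source = "ground_truth"),
    truth_celltypes = celltypes,
    truth_memory = tibble(gene_id = gene_ids,
                          category = factor(role, levels = c("quantitative",
                                                             "qualitative",
                                                             "none"))),
    config = cfg
  ), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d genes x %d cells, %d lineages, %d memory genes\n",
              nrow(x$counts$values), ncol(x$counts$values),
              x$config$n_lineages, sum(x$truth_memory$category != "none")))
  invisible(x)
}

#' Multinomial read downsampling
#'
#' Thins each cell's reads to a fraction of its total: conceptually all reads
#' of a cell are pooled and a fraction of them resampled, implemented as one
#' multinomial draw per cell with probabilities proportional to the observed
#' counts.
#'
#' @param m A raw (count) [expression_matrix()].
#' @param fraction Fraction of reads to keep, in (0, 1].
#' @param seed Integer seed.
#' @return A raw [expression_matrix()] with thinned counts.
#' @export
downsample_reads <- function(m, fraction, seed = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$normalized) abort("downsample raw counts, not normalized values",
                          class = "memlin_parameter_error")
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "memlin_parameter_error")
  }
  if (fraction == 1) return(m)
  v <- as_dense(m)
  withr::with_seed(seed, {
    out <- apply(v, 2, function(x) {
      tot <- sum(x)
      if (tot == 0) return(x)
      rmultinom(1, size = round(fraction * tot), prob = x)[, 1]
    })
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits the 10x-style MatrixMarket triple plus `truth_lineages.tsv`,
#' `truth_celltypes.tsv` (if present) and `truth_memory.tsv`. Reading the
#' files back reproduces the dataset's matrices and annotations.
#'
#' @param ds A `simulated_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(ds$counts, dir, format = "mtx")
  readr::write_tsv(as_tibble(ds$truth_lineages),
                   file.path(dir, "truth_lineages.tsv"))
  if (!is.null(ds$truth_celltypes)) {
    readr::write_tsv(ds$truth_celltypes, file.path(dir, "truth_celltypes.tsv"))
  }
  readr::write_tsv(ds$truth_memory, file.path(dir, "truth_memory.tsv"))
  invisible(dir)
}
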