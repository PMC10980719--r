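# memlin

Cell lineage inference from single-cell RNA-seq, without barcodes.

Cells related over a few divisions (a small lineage, or clone) inherit part of
their transcriptional state: a sizeable set of genes — *memory genes* — keeps a
characteristic expression level within a lineage while varying strongly between
lineages. `memlin` exploits this heritable signal to reconstruct small-to-medium
cell lineages directly from a UMI count matrix, for datasets where genetic
barcoding (LARRY, CellTag, mitochondrial variants) is unavailable or incomplete.
It is aimed at single-cell analysts studying clonal structure, cell-fate
decisions and the heritability of expression programs.

## The method

Given a genes × cells count matrix, each cell scaled to a fixed depth
(default 40,000, RPM-style):

1. **Gene selection.** For each gene compute the mean expression m̄ and
   CV² = σ²/m̄², then the mean-corrected variability: the residual of an OLS fit
   of log₁₀CV² on log₁₀m̄ across expressed genes. With percentile ranks
   `mean_q` and `var_q` (0–100), a gene is kept when

   `(mean_q ≥ 98) ∨ (mean_q ≥ 90 ∧ var_q ≥ 40) ∨ (mean_q ≥ 60 ∧ var_q ≥ 90)`,

   i.e. the 2% highest expressed genes, the 60% most variable of the 10%
   highest expressed, and the 10% most variable of the 40% highest expressed.
   This strongly enriches memory genes.

2. **Repeated iterative clustering.** In each of R repetitions (default 100),
   75% of the selected genes are drawn at random; cells are split into 2
   clusters by hierarchical clustering (`ward.D2` linkage on the correlation
   distance d = 1 − Pearson r) and each cluster is re-split recursively —
   distances recomputed over its own cells — until clusters hold at most 2–3
   cells. Cell pairs sharing a terminal cluster are recorded. Summing over
   repetitions gives a symmetric **confidence matrix**: pair (i, j) has
   confidence c ∈ [0, R] if it co-clustered in c repetitions.

3. **Lineage assignment.** Pairs at or above a confidence threshold (default
   50) form a graph; predicted lineages are its connected components, which
   may exceed the terminal cluster size.

Predictions are scored against ground truth on unordered cell pairs:
precision TP/(TP+FP), sensitivity TP/(TP+FN), FPR FP/(FP+TN), and ROC AUC with
confidence as the ranking score. Given any lineage annotation (barcode truth or
predictions), **memory genes** are called per gene by comparing the CV² of
per-lineage mean expression to 20 size-matched random groupings
(p = (1+b)/(1+20), one-sided) and categorized by the skewness of their
expression: quantitative (< 3, graded heritable levels) vs. qualitative (≥ 3,
on/off across lineages).

A lineage-structured count simulator (log-normal rates, planted quantitative /
qualitative memory genes, optional cell-type programs, Poisson sampling) makes
the full pipeline testable end to end without external data; see the methods
vignette (`vignettes/memory-lineage-inference.Rmd`).

## Worked example

```r
library(memlin)

ds <- simulate_dataset(simulation_config(n_lineages = 30, n_genes = 1000, seed = 7))
#> <simulated_dataset> 1000 genes x 121 cells, 30 lineages, 200 memory genes

m      <- normalize_depth(ds$counts, target_depth = 40000)
stats  <- gene_stats(m)
genes  <- select_genes(stats)          # 99 genes selected
cm     <- predict_lineages(m, genes, prediction_params(seed = 7))
#> <confidence_matrix> 121 cells, 100 repetitions, 460 pairs with confidence > 0

head(tidy(cm), 3)
#>   cell_a   cell_b   confidence
#> 1 cell0039 cell0042        100
#> 2 cell0059 cell0060        100
#> 3 cell0014 cell0015         99

lineages <- assign_lineages(cm, threshold = 50)   # 39 lineages over 99 cells

evaluate_lineages(cm, ds$truth_lineages, thresholds = c(30, 50, 70))
#>   threshold tp fp  fn   tn precision sensitivity      fpr   auc
#> 1        30 90  5 103 7062     0.947       0.466 0.000708 0.967
#> 2        50 78  2 115 7065     0.975       0.404 0.000283 0.967
#> 3        70 57  0 136 7067     1.000       0.295 0.000000 0.967

mem <- call_memory_genes(m, ds$truth_lineages, size_range = c(2, 5), seed = 7)
dplyr::count(mem, category)
#>   category         n
#> 1 quantitative   163
#> 2 qualitative     52
#> 3 none           785
```

Reading the output: at confidence ≥ 50 nearly every predicted pair is truly
clonal (precision 0.975) while ~40% of all true clonal pairs are recovered, at
a false positive rate of 3 per 10,000 non-clonal pairs. Raising the threshold
trades sensitivity for precision along the trace. The memory-gene call
recovers 215 of the ~200 planted memory genes plus borderline cases, split
into quantitative and qualitative classes.

`autoplot()` methods draw the precision/sensitivity/FPR trace
(`autoplot(ev)`), the confidence matrix heat map ordered by lineage
(`autoplot(cm, order_by = ds$truth_lineages)`) and the CV²-vs-mean selection
plot (`plot_gene_selection(stats, genes)`).

The same pipeline is available from a shell via the installed script
(`exec/memlin`): subcommands `simulate`, `select-genes`, `predict`, `memory`,
`eval` and `pipeline`, each writing a JSON run manifest (command, parameters,
seed, input checksums, version) next to its outputs.

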