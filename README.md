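# kinwave

Time-course single-cell RNA-seq analysis for two-arm regeneration
experiments: kinetic TDEG modules, pseudotime expression waves, per-cell
gene-set AUC scores, and differential ligand–receptor crosstalk.

## The problem

Drug-induced hair follicle regeneration (and similar perturbation studies)
is typically profiled as a two-arm design — vehicle vs treated — sampled at
a few time points spanning the telogen-to-anagen transition (here days 0, 3,
9, 15). The questions are temporal: which genes respond over time within
each cell type, what kinetic shape does the response take, how does the
stem-cell differentiation continuum shift, which gene programs gain or lose
activity per cell, and which cell–cell signaling events change between arms.
`kinwave` implements that analysis chain as tested, reusable R functions,
together with a ground-truthed negative-binomial simulator of the full
design so every stage can be validated against planted truth.

## What it computes

- **TDEGs** (time-dependent differentially expressed genes): for each
  (cell type, arm), a Wilcoxon rank-sum test between every pair of time
  points on log-normalized expression, with Benjamini–Hochberg adjustment
  per day-pair family. A gene is a TDEG iff `|avg_logFC| > 0.25` and
  `p_val_adj < 0.05` in at least one pair, where
  `avg_logFC = ln[(mean(e^xA − 1) + 1) / (mean(e^xB − 1) + 1)]`.
- **Kinetic modules**: gene-wise natural-cubic-spline fits of expression on
  the continuous day axis, row-standardized and clustered with
  `hclust(..., "ward.D2")` into four modules, which are matched bijectively
  to the four canonical kinetics — decreasing, bell, valley, increasing —
  by maximum-correlation assignment and renumbered 1–4 so module identities
  are comparable across cell types. Shared-program genes are those assigned
  to a given module in at least *k* cell types.
- **Pseudotime and wave-DEGs**: a transparent root-anchored ordering (PCA,
  symmetric k-NN graph, shortest-path distance from the root population's
  centroid cell, rescaled to [0, 1]); per-gene negative-binomial spline
  likelihood-ratio tests against pseudotime; genes with `q < 0.05` and
  expression ratio `> 10%` ranked, capped at the top 1000, and Ward-clustered
  into three waves numbered by peak position (early → late).
- **Gene-set activity**: per-cell recovery-curve AUC over the top 5% of each
  cell's expression ranking (ties averaged, deterministic), in [0, 1]; and
  weighted Kolmogorov–Smirnov gene-set enrichment (ES, NES, permutation p,
  sign-matched NES-ratio FDR).
- **Crosstalk**: ligand–receptor scores as the product of Tukey trimeans of
  ligand (sender type) and receptor (receiver type) expression within an
  arm, with label-permutation p-values, and the treated-minus-vehicle
  significant-event-count delta per (sender, receiver).

## Worked example

```r
library(kinwave)
cfg <- sim_config(n_cell_types = 2, cells_per_condition = 40, seed = 42)
ds  <- simulate_dataset(cfg)
qc  <- qc_filter(ds$counts, meta = ds$meta)
qc$counts
#> count_matrix: 1000 genes x 640 cells (10 mitochondrial genes)

lognorm <- normalize_log(qc$counts)
deg <- find_time_degs(lognorm, qc$meta, cell_type = "T1", group = "treated")
length(deg$tdeg_genes)
#> [1] 169

sub <- qc$meta$cell_type == "T1" & qc$meta$group == "treated"
curves <- smooth_time_curves(lognorm[deg$tdeg_genes, qc$meta$cell_id[sub]],
                             qc$meta$day[sub])
mods <- label_module_shapes(cluster_kinetic_modules(curves, k = 4))
table(module = mods$modules, shape = mods$shape_labels[mods$modules])
#>       shape
#> module bell decreasing increasing valley
#>      1    0         44          0      0
#>      2   48          0          0      0
#>      3    0          0          0     26
#>      4    0          0         51      0
```

The QC step retained 640 of 640 simulated cells (the generator's library
sizes are comfortably inside the 500–5,000 detected-gene window); 169 of the
genes in cell type T1 passed the TDEG thresholds in the treated arm, and the
four recovered modules carry the four canonical shapes. Against the planted
module labels the recovered partition has an adjusted Rand index of 0.945 —
the residual disagreement comes from valley-shaped genes whose dip is too
shallow to clear the fold-change cutoff at the sampled days.

A thin command-line wrapper over the same functions is installed at
`inst/cli/kinwave.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","kinwave.R",package="kinwave"))')" \
  pipeline --in fixture_dir --out results_dir --seed 7
```

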