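#' Run the full time-course analysis pipeline on a fixture directory
#'
#' End-to-end driver used by the command-line interface: reads a fixture
#' (see [read_fixture()]), applies QC and log-normalization, annotates cell
#' types from the marker table (or uses provided labels), discovers TDEGs
#' and kinetic modules per (cell type, arm), computes shared-module genes,
#' orders cells in pseudotime from a root population, selects and clusters
#' wave-DEGs, scores gene sets per cell, and counts differential
#' ligand-receptor events between the arms. All outputs are written as TSV
#' under `out_dir`; every stochastic step is driven by `seed`, so a fixed
#' seed yields byte-identical outputs.
#'
#' @param in_dir fixture directory (matrix.mtx / features.tsv / barcodes.tsv
#'   / cellmeta.tsv, optional markers.tsv, truth.json).
#' @param out_dir output directory (created).
#' @param seed integer master seed.
#' @param min_genes,max_genes,max_mito QC thresholds.
#' @param lfc_min,padj_max TDEG thresholds.
#' @param k_modules number of kinetic modules.
#' @param df spline degrees of freedom.
#' @param root_label root population for pseudotime (default: first cell
#'   type in the metadata).
#' @param n_top,k_waves wave-DEG selection size and cluster count.
#' @param gmt optional GMT path of gene sets to score.
#' @param lr_pairs optional TSV path of ligand-receptor pairs.
#' @param n_perm permutations for the crosstalk tests.
#' @return (invisibly) a list of the main result objects.
#' @export
run_pipeline <- function(in_dir, out_dir, seed = 1L,
                         min_genes = 500L, max_genes = 5000L,
                         max_mito = 0.20, lfc_min = 0.25, padj_max = 0.05,
                         k_modules = 4L, df = 3L, root_label = NULL,
                         n_top = 1000L, k_waves = 3L, gmt = NULL,
                         lr_pairs = NULL, n_perm = 100L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  fx <- read_fixture(in_dir)
  qc <- qc_filter(fx$counts, meta = fx$meta, min_genes = min_genes,
                  max_genes = max_genes, max_mito = max_mito)
  jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  lognorm <- normalize_log(qc$counts)
  meta <- qc$meta

  if (!is.null(fx$markers) && nrow(fx$markers)) {
    ann <- annotate_by_markers(lognorm, fx$markers)
    meta$cell_type_called <- ann$cell_type[match(meta$cell_id, ann$cell_id)]
    tsv(ann, "annotation.tsv")
  }
  if (!"cell_type" %in% names(meta))
    stopf("cell metadata must carry a cell_type column")
  tsv(meta, "cellmeta_qc.tsv")

  groups <- sort(unique(meta$group))
  types <- sort(unique(meta$cell_type))

  deg_tables <- list(); assignments <- list()
  for (g in groups) {
    for (ct in types) {
      res <- tryCatch(
        find_time_degs(lognorm, meta, cell_type = ct, group = g,
                       lfc_min = lfc_min, padj_max = padj_max),
        error = function(e) NULL)
      if (is.null(res)) next
      deg_tables[[paste(g, ct)]] <- res$records
      if (length(res$tdeg_genes) >= k_modules) {
        sub <- meta$cell_type == ct & meta$group == g
        curves <- smooth_time_curves(
          lognorm[res$tdeg_genes, meta$cell_id[sub], drop = FALSE],
          meta$day[sub], df = df)
        asg <- cluster_kinetic_modules(curves, k = k_modules)
        if (k_modules == 4L) asg <- label_module_shapes(asg)
        assignments[[paste(g, ct, sep = "|")]] <- data.frame(
          group = g, cell_type = ct, gene = names(asg$modules),
          module = as.integer(asg$modules),
          shape = if (!is.null(asg$shape_labels))
            asg$shape_labels[as.character(asg$modules)] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(deg_tables)) tsv(do.call(rbind, deg_tables), "deg_records.tsv")
  mod_df <- if (length(assignments)) do.call(rbind, assignments) else NULL
  if (!is.null(mod_df)) {
    rownames(mod_df) <- NULL
    tsv(mod_df, "modules.tsv")
    # shared genes per module within each arm, across cell types
    shared <- list()
    for (g in groups) {
      sub <- mod_df[mod_df$group == g, c("cell_type", "gene", "module")]
      for (k in 1:4) {
        sh <- shared_tdeg_genes(sub, k, min_cell_types = 2L)
        if (nrow(sh))
          shared[[paste(g, k)]] <- cbind(group = g, module = k, sh)
      }
    }
    if (length(shared)) tsv(do.call(rbind, shared), "shared_genes.tsv")
  }

  root <- root_label %||% types[1]
  pt <- pseudotime_order(lognorm, meta, root, label_col = "cell_type")
  tsv(pt$cells, "pseudotime.tsv")
  ptv <- pt$cells$pseudotime
  wave_rec <- pseudotime_deg_test(
    qc$counts$counts[, pt$cells$cell_id, drop = FALSE], ptv, df = df)
  tsv(wave_rec, "wave_deg_records.tsv")
  waves <- wave_deg_modules(wave_rec, lognorm[, pt$cells$cell_id],
                            ptv, n_top = n_top, k = k_waves, df = df)
  if (nrow(waves$selection)) tsv(waves$selection, "wave_clusters.tsv")
  comp <- binned_composition(ptv,
                             meta$cell_type[match(pt$cells$cell_id,
                                                  meta$cell_id)])
  tsv(comp, "binned_composition.tsv")

  score_out <- NULL
  if (!is.null(gmt)) {
    sets <- read_gmt(gmt)
    score_out <- aucell_score(lognorm, sets)
    tsv(data.frame(cell_id = rownames(score_out), score_out,
                   check.names = FALSE), "set_scores.tsv")
    contr <- do.call(rbind, lapply(colnames(score_out), function(nm)
      cbind(set = nm, score_contrast(score_out, meta, nm,
                                     groups = groups))))
    tsv(contr, "score_contrast.tsv")
  }

  xt <- NULL
  if (!is.null(lr_pairs)) {
    pairs <- read_lr_pairs(lr_pairs)
    res <- lapply(groups, function(g)
      crosstalk_events(lognorm, meta, pairs, g, n_perm = n_perm,
                       seed = seed))
    names(res) <- groups
    for (g in groups) tsv(res[[g]], paste0("lr_events_", g, ".tsv"))
    if (length(groups) == 2L) {
      xt <- interaction_delta(res[[1]], res[[2]])
      tsv(xt$delta, "lr_delta.tsv")
      tsv(xt$pairs, "lr_pairs_union.tsv")
    }
  }

  invisible(list(qc = qc, meta = meta, modules = mod_df,
                 pseudotime = pt, waves = waves, scores = score_out,
                 crosstalk = xt))
}
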