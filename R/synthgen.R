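#' Simulation configuration for a two-arm time-course scRNA-seq design
#'
#' Builds and validates the configuration driving [simulate_dataset()]. The
#' defaults emulate a two-arm (vehicle vs treated) experiment sampled at days
#' 0 (baseline), 3 (priming), 9 (pigmentation) and 15 (full anagen), with
#' four planted kinetic gene programs, per-type marker genes and a
#' mitochondrial gene block for QC realism.
#'
#' @param n_genes total number of genes.
#' @param n_cell_types number of cell types.
#' @param cells_per_condition cells simulated for every (type, day, group).
#' @param days strictly increasing integer time points.
#' @param groups treatment-arm labels; first is the reference arm.
#' @param genes_per_module genes planted in each of the 4 kinetic modules
#'   (length 1 or 4).
#' @param amplitude peak fold change of each module (length 1 or 4), or a
#'   4 x 2 matrix with one column per group.
#' @param nb_dispersion negative-binomial size parameter theta (> 0); counts
#'   have variance mu + mu^2/theta.
#' @param libsize_lognormal c(meanlog, sdlog) of per-cell library-size
#'   factors.
#' @param mito_fraction c(mean, sd) of the per-cell mitochondrial proportion.
#' @param n_mito_genes size of the flagged mitochondrial gene block.
#' @param markers_per_type marker genes injected per cell type.
#' @param marker_boost fold boost of a marker in its own type.
#' @param baseline_lognormal c(meanlog, sdlog) of per-gene baseline means.
#' @param seed integer RNG seed; identical seed gives bit-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000L,
                       n_cell_types = 3L,
                       cells_per_condition = 50L,
                       days = c(0L, 3L, 9L, 15L),
                       groups = c("vehicle", "treated"),
                       genes_per_module = 50L,
                       amplitude = 4,
                       nb_dispersion = 2,
                       libsize_lognormal = c(0, 0.3),
                       mito_fraction = c(0.05, 0.02),
                       n_mito_genes = 10L,
                       markers_per_type = 10L,
                       marker_boost = 8,
                       baseline_lognormal = c(log(2), 0.5),
                       seed = 1L) {
  genes_per_module <- rep_len(as.integer(genes_per_module), 4L)
  if (is.matrix(amplitude)) {
    if (!all(dim(amplitude) == c(4L, length(groups))))
      stopf("amplitude matrix must be 4 x %d (modules x groups)", length(groups))
    amp <- amplitude
  } else {
    amp <- matrix(rep_len(as.numeric(amplitude), 4L), nrow = 4L,
                  ncol = length(groups))
  }
  colnames(amp) <- groups
  if (any(amp <= 0)) stopf("all amplitudes must be > 0")
  if (nb_dispersion <= 0) stopf("nb_dispersion (theta) must be > 0")
  if (length(days) < 2L || any(diff(days) <= 0))
    stopf("days must be strictly increasing with at least 2 time points")
  if (any(mito_fraction[1] < 0 | mito_fraction[1] >= 1))
    stopf("mito_fraction mean must be in [0, 1)")
  n_planted <- sum(genes_per_module) + n_cell_types * markers_per_type +
    n_mito_genes
  if (n_planted > n_genes)
    stopf("infeasible config: %d planted genes (modules + markers + mito) exceed n_genes = %d",
          n_planted, n_genes)
  structure(list(
    n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
    cells_per_condition = as.integer(cells_per_condition),
    days = as.numeric(days), groups = as.character(groups),
    genes_per_module = genes_per_module, amplitude = amp,
    nb_dispersion = nb_dispersion,
    libsize_lognormal = as.numeric(libsize_lognormal),
    mito_fraction = as.numeric(mito_fraction),
    n_mito_genes = as.integer(n_mito_genes),
    markers_per_type = as.integer(markers_per_type),
    marker_boost = as.numeric(marker_boost),
    baseline_lognormal = as.numeric(baseline_lognormal),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Kinetic expression template for the four canonical modules
#'
#' Multiplier applied to a gene's baseline mean as a function of time.
#' All templates anchor at 1 on the first day. Module 1 decays
#' monotonically towards 1/amplitude; module 2 is a bell (interior
#' maximum reaching `amplitude`); module 3 is a valley (interior minimum
#' at 1/amplitude, recovering towards baseline); module 4 rises
#' monotonically to `amplitude` in the treated arm but plateaus at its
#' second-day value in the reference (vehicle) arm.
#'
#' @param module_id kinetic module, integer in 1..4.
#' @param day time point(s); must lie within `range(days)`.
#' @param group arm label; only module 4 distinguishes arms (the first
#'   element of `groups` is the plateauing reference arm).
#' @param amplitude peak fold change (>= 1).
#' @param days the configured design days (default 0, 3, 9, 15).
#' @param groups arm labels, reference arm first.
#' @return numeric multiplier(s), all > 0, equal to 1 at `day = days[1]`.
#' @export
kinetic_template <- function(module_id, day, group = "treated", amplitude = 4,
                             days = c(0, 3, 9, 15),
                             groups = c("vehicle", "treated")) {
  if (!(length(module_id) == 1L && module_id %in% 1:4))
    stopf("unknown module id '%s': must be 1, 2, 3 or 4", toString(module_id))
  if (!(group %in% groups))
    stopf("unknown group '%s': expected one of %s", group, toString(groups))
  if (any(day < min(days) | day > max(days)))
    stopf("day outside the configured design range [%g, %g]",
          min(days), max(days))
  if (amplitude < 1) stopf("amplitude must be >= 1")
  d0 <- min(days)
  dmax <- max(days) - d0
  t <- day - d0
  A <- amplitude
  if (module_id == 1L) {
    tau <- dmax / 3
    return((1 + (A - 1) * exp(-t / tau)) / A)
  }
  centre <- 0.4 * dmax
  sigma <- 0.15 * dmax
  g <- function(x) exp(-(x - centre)^2 / (2 * sigma^2))
  if (module_id == 2L) {
    return(1 + (A - 1) * (g(t) - g(0)) / (1 - g(0)))
  }
  if (module_id == 3L) {
    return(1 - (1 - 1 / A) * (g(t) - g(0)) / (1 - g(0)))
  }
  # module 4: saturating rise, truncated at the second design day in the
  # reference arm
  tau4 <- 0.4 * dmax
  s <- function(x) (1 - exp(-x / tau4)) / (1 - exp(-dmax / tau4))
  tt <- if (group == groups[1]) pmin(t, days[2] - d0) else t
  1 + (A - 1) * s(tt)
}

#' Simulate a ground-truthed time-course scRNA-seq dataset
#'
#' Draws a gene x cell negative-binomial count matrix whose mean structure is
#' `baseline_g * libsize_c * kinetic_template(...) * marker_boost`, with a
#' flagged mitochondrial block calibrated so each cell's expected
#' mitochondrial read proportion matches its sampled target.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `counts` (a [count_matrix()]), `meta` (per-cell
#'   data.frame: cell_id, group, day, cell_type), `truth` (gene_module,
#'   gene_marker_type, cell_labels, mu, markers) .
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    types <- paste0("T", seq_len(cfg$n_cell_types))
    design <- expand.grid(cell_type = types, day = cfg$days,
                          group = cfg$groups, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    n_cells <- nrow(design) * cfg$cells_per_condition
    meta <- design[rep(seq_len(nrow(design)), each = cfg$cells_per_condition), ]
    meta$cell_id <- sprintf("cell%05d", seq_len(n_cells))
    rownames(meta) <- NULL
    meta <- meta[, c("cell_id", "group", "day", "cell_type")]

    # gene universe layout
    gm <- cfg$genes_per_module
    module_genes <- unlist(lapply(1:4, function(k)
      sprintf("M%d_g%03d", k, seq_len(gm[k]))))
    gene_module <- rep(1:4, gm)
    names(gene_module) <- module_genes
    marker_genes <- character(0)
    gene_marker_type <- character(0)
    if (cfg$markers_per_type > 0L) {
      marker_genes <- unlist(lapply(types, function(tp)
        sprintf("MK_%s_g%02d", tp, seq_len(cfg$markers_per_type))))
      gene_marker_type <- rep(types, each = cfg$markers_per_type)
      names(gene_marker_type) <- marker_genes
    }
    mito_genes <- if (cfg$n_mito_genes > 0L)
      sprintf("mt-g%02d", seq_len(cfg$n_mito_genes)) else character(0)
    n_bg <- cfg$n_genes - length(module_genes) - length(marker_genes) -
      length(mito_genes)
    bg_genes <- if (n_bg > 0L) sprintf("BG_g%04d", seq_len(n_bg)) else character(0)
    genes <- c(module_genes, marker_genes, bg_genes, mito_genes)
    mito_flag <- genes %in% mito_genes

    baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_lognormal[1],
                              cfg$baseline_lognormal[2])
    names(baseline) <- genes
    libsize <- stats::rlnorm(n_cells, cfg$libsize_lognormal[1],
                             cfg$libsize_lognormal[2])

    mu <- outer(baseline, libsize)
    dimnames(mu) <- list(genes, meta$cell_id)

    # kinetic factors: one column of factors per design condition
    for (k in if (n_cells > 0L) 1:4 else integer(0)) {
      idx <- which(gene_module == k)
      if (!length(idx)) next
      gidx <- match(names(gene_module)[idx], genes)
      fac <- mapply(function(d, g)
        kinetic_template(k, d, g, cfg$amplitude[k, g], cfg$days, cfg$groups),
        meta$day, meta$group)
      mu[gidx, ] <- mu[gidx, ] * rep(fac, each = length(gidx))
    }
    # marker boost in own type
    if (length(marker_genes) && n_cells > 0L) {
      for (tp in types) {
        mk <- names(gene_marker_type)[gene_marker_type == tp]
        cells_tp <- meta$cell_type == tp
        mu[match(mk, genes), cells_tp] <- mu[match(mk, genes), cells_tp] *
          cfg$marker_boost
      }
    }
    # mitochondrial block: give it a Dirichlet-weighted share of each cell's
    # non-mito mean so the expected mito proportion equals the cell's target
    if (length(mito_genes) && n_cells > 0L) {
      m <- cfg$mito_fraction[1]
      v <- cfg$mito_fraction[2]^2
      p_cell <- if (v <= 0) rep(m, n_cells) else {
        shape <- m * (1 - m) / v - 1
        stats::rbeta(n_cells, pmax(m * shape, 0.5), pmax((1 - m) * shape, 0.5))
      }
      p_cell <- pmin(pmax(p_cell, 0.001), 0.6)
      w <- stats::rgamma(length(mito_genes), shape = 2)
      w <- w / sum(w)
      nonmito_total <- colSums(mu[!mito_flag, , drop = FALSE])
      mito_total <- nonmito_total * p_cell / (1 - p_cell)
      mu[mito_flag, ] <- outer(w, mito_total)
    }

    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = cfg$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    cm <- count_matrix(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                   "CsparseMatrix"),
                       mito_flag = mito_flag)
    markers <- if (length(marker_genes))
      data.frame(cell_type = gene_marker_type, gene = marker_genes,
                 row.names = NULL, stringsAsFactors = FALSE)
    else data.frame(cell_type = character(0), gene = character(0))
    truth <- list(gene_module = gene_module,
                  gene_marker_type = gene_marker_type,
                  cell_labels = meta, mu = mu, markers = markers,
                  config = cfg)
    list(counts = cm, meta = meta, truth = truth)
  })
}

#' Write a simulated dataset to disk as plain-text fixture files
#'
#' Emits `matrix.mtx` (MatrixMarket coordinate integer), 10x-style
#' `features.tsv` (id, name, type) and `barcodes.tsv`, `cellmeta.tsv`,
#' `markers.tsv`, and `truth.json` (gene-level ground truth and cell labels;
#' the dense expected-mean matrix stays in memory only).
#'
#' @param dataset result of [simulate_dataset()] (or any list with `counts`
#'   and `meta`).
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", dir)
  }
  cm <- dataset$counts
  m <- cm$counts
  trip <- Matrix::summary(m)
  con <- file.path(dir, "matrix.mtx")
  header <- c("%%MatrixMarket matrix coordinate integer general",
              sprintf("%d %d %d", nrow(m), ncol(m), nrow(trip)))
  body <- if (nrow(trip)) sprintf("%d %d %d", trip$i, trip$j,
                                  as.integer(trip$x)) else character(0)
  writeLines(c(header, body), con)
  feat <- data.frame(id = cm$gene_names, name = cm$gene_names,
                     type = ifelse(cm$mito_flag, "Mito", "Gene Expression"))
  utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(dataset$meta, file.path(dir, "cellmeta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    jsonlite::write_json(list(
      gene_module = as.list(tr$gene_module),
      gene_marker_type = as.list(tr$gene_marker_type),
      cell_labels = tr$cell_labels), file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(tr$markers) && nrow(tr$markers))
      utils::write.table(tr$markers, file.path(dir, "markers.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()] (or 10x-style MTX)
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#'   and optionally `cellmeta.tsv`, `markers.tsv`, `truth.json`.
#' @return list with `counts` ([count_matrix()]), `meta`, `markers`, `truth`
#'   (the latter three `NULL` when absent).
#' @export
read_fixture <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stopf("no matrix.mtx under '%s'", dir)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                            header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(feat[[1]], barcodes)
  mito <- if (ncol(feat) >= 3) feat[[3]] == "Mito" else NULL
  meta <- markers <- truth <- NULL
  f <- file.path(dir, "cellmeta.tsv")
  if (file.exists(f))
    meta <- utils::read.table(f, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  f <- file.path(dir, "markers.tsv")
  if (file.exists(f))
    markers <- utils::read.table(f, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
  f <- file.path(dir, "truth.json")
  if (file.exists(f)) {
    truth <- jsonlite::read_json(f, simplifyVector = TRUE)
    if (length(truth$gene_module))
      truth$gene_module <- unlist(truth$gene_module)
    if (length(truth$gene_marker_type))
      truth$gene_marker_type <- unlist(truth$gene_marker_type)
  }
  list(counts = count_matrix(m, mito_flag = mito), meta = meta,
       markers = markers, truth = truth)
}
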