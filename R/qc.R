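#' Construct a sparse gene x cell count container
#'
#' Thin validated wrapper around a sparse integer count matrix carrying gene
#' names, cell ids and a per-gene mitochondrial flag. When no flag is given,
#' mitochondrial genes are identified by the mouse-style "mt-" name prefix
#' (case-insensitive).
#'
#' @param counts gene x cell matrix (coerced to sparse) of non-negative
#'   integers with unique dimnames.
#' @param mito_flag logical per-gene flag, or `NULL` to derive from names.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, mito_flag = NULL) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  # degenerate 0-extent dimensions may legitimately carry no names
  if ((is.null(rownames(m)) && nrow(m) > 0L) ||
      (is.null(colnames(m)) && ncol(m) > 0L))
    stopf("counts must carry gene (row) and cell (column) names")
  gene_names <- rownames(m) %||% character(0)
  cell_ids <- colnames(m) %||% character(0)
  if (anyDuplicated(gene_names)) stopf("gene names must be unique")
  if (anyDuplicated(cell_ids)) stopf("cell ids must be unique")
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    stopf("counts must be non-negative integers")
  if (is.null(mito_flag)) {
    mito_flag <- grepl("^mt-", rownames(m), ignore.case = TRUE)
  }
  stopifnot(length(mito_flag) == nrow(m))
  structure(list(counts = m, gene_names = gene_names,
                 cell_ids = cell_ids, mito_flag = as.logical(mito_flag)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_flag)))
  invisible(x)
}

#' Quality-control filtering of cells
#'
#' Retains cells detecting between `min_genes` and `max_genes` genes
#' (inclusive on both ends) with a mitochondrial read proportion of at most
#' `max_mito`. These are the standard per-cell QC covariates; thresholds are
#' read inclusively ("between 500 and 5,000" as a closed interval, "no more
#' than 20%" as <= 0.20) and the reading is recorded in the report.
#'
#' @param x a [count_matrix()].
#' @param meta optional per-cell data.frame with a `cell_id` column, subset
#'   alongside the matrix.
#' @param min_genes,max_genes closed bounds on genes detected per cell.
#' @param max_mito maximum mitochondrial proportion (inclusive).
#' @return list with `counts` (filtered [count_matrix()]), `meta` (per-cell
#'   data.frame including `n_genes_detected` and `mito_pct`), and `report`
#'   (counts removed per criterion). Removing every cell yields an empty
#'   matrix plus a warning, not an error.
#' @export
qc_filter <- function(x, meta = NULL, min_genes = 500L, max_genes = 5000L,
                      max_mito = 0.20) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  n_detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mito_counts <- Matrix::colSums(m[x$mito_flag, , drop = FALSE])
  mito_pct <- ifelse(total > 0, mito_counts / total, 0)

  pass_low <- n_detected >= min_genes
  pass_high <- n_detected <= max_genes
  pass_mito <- mito_pct <= max_mito
  keep <- pass_low & pass_high & pass_mito

  report <- list(
    n_cells_in = ncol(m),
    n_retained = sum(keep),
    n_removed = sum(!keep),
    n_below_min_genes = sum(!pass_low),
    n_above_max_genes = sum(!pass_high),
    n_above_max_mito = sum(!pass_mito),
    thresholds = list(min_genes = min_genes, max_genes = max_genes,
                      max_mito = max_mito, inclusive = TRUE)
  )
  if (!any(keep))
    warnf("qc_filter removed all %d cells", ncol(m))

  kept <- count_matrix(m[, keep, drop = FALSE],
                       mito_flag = x$mito_flag)
  cm <- data.frame(cell_id = x$cell_ids[keep],
                   n_genes_detected = as.integer(n_detected[keep]),
                   mito_pct = as.numeric(mito_pct[keep]),
                   stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    stopifnot("cell_id" %in% names(meta))
    cm <- merge(cm, meta, by = "cell_id", sort = FALSE)
    cm <- cm[match(kept$cell_ids, cm$cell_id), , drop = FALSE]
    rownames(cm) <- NULL
  }
  list(counts = kept, meta = cm, report = report)
}

#' Library-size log-normalization
#'
#' value = ln(count * scale / library_size + 1), the standard log-normalized
#' expression used by all downstream rank and spline machinery. Sparsity is
#' preserved (zeros map to zero).
#'
#' @param x a [count_matrix()] or sparse/dense count matrix with dimnames.
#' @param scale size factor target (default 1e4).
#' @return sparse dgCMatrix of log-normalized expression.
#' @export
normalize_log <- function(x, scale = 1e4) {
  m <- if (inherits(x, "count_matrix")) x$counts else
    methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  libsize <- Matrix::colSums(m)
  if (any(libsize == 0)) {
    bad <- colnames(m)[libsize == 0]
    stopf("cell(s) with zero library size cannot be normalized: %s",
          toString(utils::head(bad, 5)))
  }
  out <- m
  if (length(out@x)) {
    cell_of <- rep(seq_len(ncol(out)), diff(out@p))
    out@x <- log1p(out@x * scale / libsize[cell_of])
  }
  out
}

#' Reference marker table for mouse skin cell types
#'
#' Canonical cell-type-specific markers for the 15 skin/hair-follicle
#' populations used in annotation of real data: basal (Krt14), mitotic basal
#' (Mki67), spinous (Krt1), granular (Flg2), upper hair follicle (Krt79),
#' bulge (Lhx2, Cd34), germ layer (Cdh3, Lef1), sebaceous gland (Scd1),
#' endothelial (Pecam1), smooth muscle (Acta2), fibroblast (Pdgfra),
#' macrophages (Cd68; Cd163), Langerhans (Cd207) and T cells (Cd3g).
#'
#' @return data.frame with columns `cell_type`, `gene`.
#' @export
default_marker_table <- function() {
  data.frame(
    cell_type = c("BC", "MC", "SC", "GC", "UHF", "HFB", "HFB", "GL", "GL",
                  "SG", "EC", "SM", "FB", "Mac1", "Mac2", "LC", "TC"),
    gene = c("Krt14", "Mki67", "Krt1", "Flg2", "Krt79", "Lhx2", "Cd34",
             "Cdh3", "Lef1", "Scd1", "Pecam1", "Acta2", "Pdgfra", "Cd68",
             "Cd163", "Cd207", "Cd3g"),
    stringsAsFactors = FALSE
  )
}

#' Marker-based cell-type annotation
#'
#' Scores each cell for each cell type as the mean of its markers'
#' z-scored (across cells) log-normalized expression; the label is the
#' argmax, with deterministic ties broken by marker-table order. The margin
#' (top score minus runner-up) flags low-confidence calls.
#'
#' @param lognorm gene x cell log-normalized matrix (from [normalize_log()]).
#' @param markers data.frame (`cell_type`, `gene`) or a named list of marker
#'   vectors; table order fixes the tie-break priority.
#' @return data.frame: `cell_id`, `cell_type`, `margin`, `low_confidence`,
#'   plus the full score matrix as attribute `"scores"`.
#' @export
annotate_by_markers <- function(lognorm, markers) {
  if (is.list(markers) && !is.data.frame(markers)) {
    markers <- data.frame(
      cell_type = rep(names(markers), lengths(markers)),
      gene = unlist(markers, use.names = FALSE), stringsAsFactors = FALSE)
  }
  type_order <- unique(markers$cell_type)
  present <- markers$gene %in% rownames(lognorm)
  if (any(!present)) {
    missing_by_type <- split(markers$gene[!present], markers$cell_type[!present])
    markers <- markers[present, , drop = FALSE]
  }
  resolvable <- type_order[type_order %in% markers$cell_type]
  dropped <- setdiff(type_order, resolvable)
  if (length(dropped))
    warnf("cell type(s) with no resolvable marker excluded: %s",
          toString(dropped))
  if (!length(resolvable)) stopf("no marker gene found in the gene universe")

  mk_expr <- as.matrix(lognorm[markers$gene, , drop = FALSE])
  z <- standardize_rows(mk_expr)$std
  scores <- do.call(rbind, lapply(resolvable, function(tp) {
    colMeans(z[markers$cell_type == tp, , drop = FALSE])
  }))
  rownames(scores) <- resolvable

  top <- apply(scores, 2L, max)
  label_idx <- apply(scores, 2L, which.max)  # first max = table order tie-break
  runner <- apply(scores, 2L, function(s) {
    if (length(s) < 2L) return(-Inf)
    max(s[-which.max(s)])
  })
  margin <- top - runner
  out <- data.frame(cell_id = colnames(lognorm),
                    cell_type = resolvable[label_idx],
                    margin = as.numeric(margin),
                    low_confidence = margin <= 0,
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- t(scores)
  out
}
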