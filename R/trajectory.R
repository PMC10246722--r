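#' Root-anchored graph pseudotime
#'
#' Orders cells along a single lineage: cells are projected onto `d`
#' principal components, a symmetric k-nearest-neighbor graph with Euclidean
#' edge weights is built, and pseudotime is the shortest-path graph distance
#' from the root population's centroid-nearest cell, rescaled to \[0, 1\].
#' This is a deliberately transparent ordering with the same contract as
#' tree-based embeddings (root-anchored monotone progression along the
#' dominant expression gradient); it does not infer branches.
#'
#' @param lognorm gene x cell log-normalized matrix.
#' @param meta per-cell data.frame with `cell_id` and the label column.
#' @param root_label label of the root population (pseudotime origin).
#' @param d number of principal components (default 10).
#' @param k_nn neighbors per cell in the graph (default 15).
#' @param genes_use `"hvg"` (top `n_hvg` most variable genes), `"all"`, or a
#'   character vector of gene names (e.g. curated lineage markers).
#' @param n_hvg number of highly variable genes when `genes_use = "hvg"`.
#' @param label_col metadata column holding the population labels.
#' @return object of class `pseudotime_result`: data.frame `cells`
#'   (`cell_id`, `pseudotime`, `disconnected`), `root_label`, `root_cell`,
#'   `d`, `method` metadata.
#' @export
pseudotime_order <- function(lognorm, meta, root_label, d = 10L, k_nn = 15L,
                             genes_use = "hvg", n_hvg = 2000L,
                             label_col = "cell_type") {
  stopifnot(label_col %in% names(meta))
  labels <- meta[[label_col]][match(colnames(lognorm), meta$cell_id)]
  if (!any(labels == root_label, na.rm = TRUE))
    stopf("root label '%s' not found among cell labels", root_label)
  n <- ncol(lognorm)
  if (n < k_nn + 1L) stopf("need at least k_nn + 1 = %d cells", k_nn + 1L)

  if (identical(genes_use, "hvg")) {
    v <- apply(as.matrix(lognorm), 1L, stats::var)
    genes <- rownames(lognorm)[order(-v)][seq_len(min(n_hvg, nrow(lognorm)))]
  } else if (identical(genes_use, "all")) {
    genes <- rownames(lognorm)
  } else {
    genes <- intersect(genes_use, rownames(lognorm))
    if (!length(genes)) stopf("none of the requested genes are present")
  }
  x <- t(as.matrix(lognorm[genes, , drop = FALSE]))
  d_eff <- min(d, ncol(x) - 1L, nrow(x) - 1L)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = d_eff)$x

  # root = member of the root population nearest to the population centroid
  root_cells <- which(labels == root_label)
  centroid <- colMeans(pcs[root_cells, , drop = FALSE])
  root_cell <- root_cells[which.min(colSums((t(pcs[root_cells, , drop = FALSE])
                                             - centroid)^2))]

  dm <- as.matrix(stats::dist(pcs))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[2:(k_nn + 1L)]
    adj[i, nb] <- dm[i, nb]
  }
  adj <- pmax(adj, t(adj))  # symmetric union; weights identical both ways
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  gd <- as.numeric(igraph::distances(g, v = root_cell))
  disconnected <- !is.finite(gd)
  if (all(disconnected)) stopf("root cell is fully disconnected")
  mx <- max(gd[!disconnected])
  pt <- if (mx > 0) gd / mx else gd
  pt[disconnected] <- 1
  cells <- data.frame(cell_id = colnames(lognorm), pseudotime = pt,
                      disconnected = disconnected, stringsAsFactors = FALSE)
  structure(list(cells = cells, root_label = root_label,
                 root_cell = colnames(lognorm)[root_cell], d = d_eff,
                 method = "pca + knn-graph shortest path"),
            class = "pseudotime_result")
}

#' Fraction of cells expressing a gene
#'
#' @param counts numeric vector of counts (or expression) for one gene.
#' @return proportion of entries > 0.
#' @export
expression_ratio <- function(counts) {
  if (!length(counts)) stopf("need at least one cell")
  mean(counts > 0)
}

# estimate the NB size parameter under the intercept-only model; ML with a
# method-of-moments fallback, clamped to a sane range
estimate_theta_null <- function(y) {
  mu <- mean(y)
  v <- stats::var(y)
  th0 <- if (is.finite(v) && v > mu) mu^2 / (v - mu) else 100
  th <- tryCatch(
    suppressWarnings(as.numeric(MASS::theta.ml(y, mu = rep(mu, length(y)),
                                               limit = 25))),
    error = function(e) th0)
  if (!is.finite(th) || th <= 0) th <- th0
  min(max(th, 1e-3), 1e5)
}

#' Spline likelihood-ratio test for pseudotime-dependent expression
#'
#' Negative-binomial regression of raw counts on a natural cubic spline
#' basis of pseudotime (log link) against an intercept-only null. The
#' dispersion is estimated once under the null and held fixed in both fits,
#' so the models are strictly nested and the statistic is non-negative;
#' p-values come from a chi-square with `df` degrees of freedom. If a fit
#' fails to converge the test falls back to Gaussian least squares on
#' log1p counts with an F-test, flagged in the output.
#'
#' @param counts integer counts for one gene across cells.
#' @param pseudotime per-cell pseudotime in \[0, 1\].
#' @param df spline degrees of freedom (default 3).
#' @return named vector `c(lrt_stat, p_val, gaussian_fallback)`.
#' @export
spline_lrt <- function(counts, pseudotime, df = 3L) {
  ok <- is.finite(pseudotime)
  y <- counts[ok]; pt <- pseudotime[ok]
  if (length(y) < df + 2L) stopf("need at least df + 2 cells")
  if (all(y == y[1])) return(c(lrt_stat = 0, p_val = 1, gaussian_fallback = 0))
  B <- splines::ns(pt, df = df)
  res <- tryCatch({
    theta <- estimate_theta_null(y)
    fam <- MASS::negative.binomial(theta)
    full <- stats::glm(y ~ B, family = fam)
    null <- stats::glm(y ~ 1, family = fam)
    if (!full$converged || !null$converged) stop("glm did not converge")
    lrt <- max(0, null$deviance - full$deviance)
    c(lrt_stat = lrt,
      p_val = stats::pchisq(lrt, df = df, lower.tail = FALSE),
      gaussian_fallback = 0)
  }, error = function(e) {
    ly <- log1p(y)
    full <- stats::lm(ly ~ B)
    null <- stats::lm(ly ~ 1)
    a <- stats::anova(null, full)
    fstat <- a$F[2]
    ss <- a$`Sum of Sq`[2]
    pv <- stats::pf(fstat, a$Df[2], full$df.residual, lower.tail = FALSE)
    c(lrt_stat = if (is.finite(ss)) max(0, ss) else 0,
      p_val = if (is.finite(pv)) pv else 1,
      gaussian_fallback = 1)
  })
  res
}

#' Test every gene for pseudotime-dependent expression
#'
#' Applies [spline_lrt()] gene-wise and assembles the wave-DEG record table
#' with BH q-values and expression ratios.
#'
#' @param counts gene x cell raw count matrix.
#' @param pseudotime per-cell pseudotime aligned with `colnames(counts)`.
#' @param df spline degrees of freedom.
#' @return data.frame: `gene`, `lrt_stat`, `p_val`, `q_value`,
#'   `expression_ratio`, `gaussian_fallback`.
#' @export
pseudotime_deg_test <- function(counts, pseudotime, df = 3L) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  m <- as.matrix(m)
  stopifnot(ncol(m) == length(pseudotime))
  res <- t(vapply(seq_len(nrow(m)), function(i)
    spline_lrt(m[i, ], pseudotime, df = df), numeric(3)))
  out <- data.frame(gene = rownames(m),
                    lrt_stat = res[, 1], p_val = res[, 2],
                    q_value = bh_adjust(res[, 2]),
                    expression_ratio = apply(m, 1L, expression_ratio),
                    gaussian_fallback = res[, 3] > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select top wave-DEGs and cluster them into expression waves
#'
#' Filters records to q_value < `q_max` and expression ratio > `ratio_min`,
#' ranks by q ascending (ties: LRT statistic descending), keeps at most
#' `n_top` genes, smooths each selected gene's log-normalized expression on a
#' pseudotime grid, Ward-clusters the standardized curves into `k` waves,
#' and renumbers waves by the pseudotime location of their peak (early = 1,
#' late = k).
#'
#' @param records output of [pseudotime_deg_test()].
#' @param lognorm gene x cell log-normalized matrix.
#' @param pseudotime per-cell pseudotime aligned with `colnames(lognorm)`.
#' @param n_top maximum number of genes kept (default 1000).
#' @param k number of wave clusters (default 3).
#' @param q_max,ratio_min strict selection thresholds (0.05, 0.10).
#' @param df,n_grid smoothing parameters passed to [smooth_time_curves()].
#' @return list: `selection` (data.frame `gene`, `wave_cluster`), `curves`
#'   (the [smooth_time_curves()] object), `peak_order` metadata. Empty
#'   selection (with a warning) when no gene passes the filters.
#' @export
wave_deg_modules <- function(records, lognorm, pseudotime, n_top = 1000L,
                             k = 3L, q_max = 0.05, ratio_min = 0.10,
                             df = 3L, n_grid = 100L) {
  stopifnot(all(c("gene", "q_value", "expression_ratio", "lrt_stat") %in%
                  names(records)))
  sig <- records[records$q_value < q_max &
                   records$expression_ratio > ratio_min, , drop = FALSE]
  if (!nrow(sig)) {
    warnf("no gene passes q < %g and expression ratio > %g", q_max, ratio_min)
    return(list(selection = data.frame(gene = character(0),
                                       wave_cluster = integer(0)),
                curves = NULL, peak_order = NULL))
  }
  sig <- sig[order(sig$q_value, -sig$lrt_stat, sig$gene), , drop = FALSE]
  sel_genes <- utils::head(sig$gene, n_top)
  curves <- smooth_time_curves(lognorm[sel_genes, , drop = FALSE],
                               pseudotime, df = df, n_grid = n_grid)
  k_eff <- min(k, length(sel_genes))
  asg <- cluster_kinetic_modules(curves, k = k_eff)
  # renumber by peak location of the cluster mean curve along pseudotime
  peak_pos <- apply(asg$mean_curves, 1L, which.max)
  new_id <- rank(peak_pos, ties.method = "first")
  wave <- as.integer(new_id[asg$modules])
  list(selection = data.frame(gene = sel_genes,
                              wave_cluster = wave[match(sel_genes,
                                                        names(asg$modules))],
                              stringsAsFactors = FALSE),
       curves = curves,
       peak_order = stats::setNames(curves$grid[peak_pos][order(new_id)],
                                    seq_len(k_eff)))
}

#' Label composition along binned pseudotime
#'
#' Partitions \[0, 1\] into `n_bins` equal half-open intervals (the last one
#' closed) and reports, per bin, the proportion of each label among its
#' cells. Empty bins are reported explicitly with `n_cells = 0`.
#'
#' @param pseudotime numeric vector in \[0, 1\].
#' @param labels per-cell labels (cell type and/or group), same length.
#' @param n_bins number of bins (default 20).
#' @return data.frame: `bin`, `bin_start`, `bin_end`, `label`, `n`,
#'   `proportion` (`label = NA`, `n = 0` rows mark empty bins).
#' @export
binned_composition <- function(pseudotime, labels, n_bins = 20L) {
  if (n_bins < 1L) stopf("n_bins must be >= 1")
  stopifnot(length(pseudotime) == length(labels))
  bin <- pmin(floor(pseudotime * n_bins) + 1L, n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  rows <- lapply(seq_len(n_bins), function(b) {
    in_bin <- which(bin == b)
    if (!length(in_bin)) {
      return(data.frame(bin = b, bin_start = edges[b], bin_end = edges[b + 1],
                        label = NA_character_, n = 0L, proportion = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tab <- table(labels[in_bin])
    data.frame(bin = b, bin_start = edges[b], bin_end = edges[b + 1],
               label = names(tab), n = as.integer(tab),
               proportion = as.numeric(tab) / length(in_bin),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
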