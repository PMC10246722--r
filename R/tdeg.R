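#' Wilcoxon rank-sum differential test with Seurat-style log fold change
#'
#' Two-sided Wilcoxon rank-sum p-value between two groups of log-normalized
#' expression values, exact (via the rank-sum null distribution) when both
#' groups have at most 8 observations and the pooled values are tie-free,
#' otherwise a normal approximation with tie and continuity corrections.
#' The fold change follows the convention under which the usual 0.25
#' threshold is meaningful: natural log of the ratio of
#' (mean back-transformed expression + 1) between groups.
#'
#' @param xA,xB numeric vectors of log-normalized expression (non-empty).
#' @return named numeric vector `c(p_val, avg_logFC)`.
#' @export
de_test <- function(xA, xB) {
  if (!length(xA) || !length(xB)) stopf("both groups must be non-empty")
  nA <- length(xA); nB <- length(xB)
  pooled <- c(xA, xB)
  r <- rank(pooled)
  W <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2  # Mann-Whitney U for group A
  ties <- anyDuplicated(pooled) > 0
  if (!ties && nA <= 8 && nB <= 8) {
    # exact two-sided p from the rank-sum null distribution
    if (W > nA * nB / 2) {
      p <- 2 * stats::pwilcox(W - 1, nA, nB, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(W, nA, nB)
    }
    p <- min(1, p)
  } else {
    n <- nA + nB
    mu <- nA * nB / 2
    tie_tab <- table(r)
    sigma2 <- (nA * nB / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                  (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- W - mu
      cc <- sign(z) * 0.5
      z <- (z - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  lfc <- log((mean(expm1(xA)) + 1) / (mean(expm1(xB)) + 1))
  c(p_val = p, avg_logFC = lfc)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Definitional step-up FDR adjustment: p(i) * m / i on the sorted p-values,
#' cumulative minimum from the largest, capped at 1, mapped back to the input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(1, adj_sorted)
  adj
}

all_day_pairs <- function(days, mode = c("all", "consecutive")) {
  mode <- match.arg(mode)
  days <- sort(unique(days))
  if (mode == "consecutive") {
    cbind(days[-length(days)], days[-1])
  } else {
    t(utils::combn(days, 2))
  }
}

#' Identify time-dependent differentially expressed genes (TDEGs)
#'
#' Runs the pairwise-time-point differential test per gene within one
#' (cell type, arm) stratum and takes the union over day pairs: a gene is a
#' TDEG iff in at least one pair |avg_logFC| > `lfc_min` and BH-adjusted
#' p < `padj_max` (both strict). BH adjustment is applied within each
#' (cell type, arm, day pair) gene family.
#'
#' @param lognorm gene x cell log-normalized matrix.
#' @param meta per-cell data.frame with `cell_id`, `day`, and (if used)
#'   `cell_type`, `group` columns matching `colnames(lognorm)`.
#' @param cell_type,group stratum selectors; `NULL` uses all cells.
#' @param lfc_min,padj_max strict thresholds (defaults 0.25, 0.05).
#' @param day_pairs `"all"` (all unordered pairs) or `"consecutive"`.
#' @param min_cells minimum cells per time point for a pair to be tested.
#' @return list: `records` (data.frame of all per-pair test results),
#'   `tdeg_genes` (character), `skipped_pairs` (data.frame of pairs lacking
#'   cells).
#' @export
find_time_degs <- function(lognorm, meta, cell_type = NULL, group = NULL,
                           lfc_min = 0.25, padj_max = 0.05,
                           day_pairs = c("all", "consecutive"),
                           min_cells = 3L) {
  sel <- rep(TRUE, nrow(meta))
  if (!is.null(cell_type)) sel <- sel & meta$cell_type == cell_type
  if (!is.null(group)) sel <- sel & meta$group == group
  meta <- meta[sel, , drop = FALSE]
  expr <- lognorm[, match(meta$cell_id, colnames(lognorm)), drop = FALSE]
  days_present <- sort(unique(meta$day))
  if (length(days_present) < 2L)
    stopf("need at least 2 time points with cells in this stratum")
  pairs <- all_day_pairs(days_present, match.arg(day_pairs))

  genes <- rownames(expr)
  recs <- list()
  skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    dA <- pairs[i, 2]; dB <- pairs[i, 1]  # later day vs earlier day
    cA <- which(meta$day == dA)
    cB <- which(meta$day == dB)
    if (length(cA) < min_cells || length(cB) < min_cells) {
      warnf("day pair (%g, %g) skipped: fewer than %d cells at a time point",
            dB, dA, min_cells)
      skipped[[length(skipped) + 1L]] <- data.frame(dayA = dA, dayB = dB)
      next
    }
    mA <- as.matrix(expr[, cA, drop = FALSE])
    mB <- as.matrix(expr[, cB, drop = FALSE])
    res <- vapply(seq_along(genes), function(g) {
      a <- mA[g, ]; b <- mB[g, ]
      if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1])
        return(c(1, 0))  # constant gene: no signal
      de_test(a, b)
    }, numeric(2))
    padj <- bh_adjust(res[1, ])
    recs[[length(recs) + 1L]] <- data.frame(
      gene = genes, cell_type = cell_type %||% NA_character_,
      group = group %||% NA_character_, dayA = dA, dayB = dB,
      avg_logFC = res[2, ], p_val = res[1, ], p_val_adj = padj,
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(0), cell_type = character(0),
               group = character(0), dayA = numeric(0), dayB = numeric(0),
               avg_logFC = numeric(0), p_val = numeric(0),
               p_val_adj = numeric(0))
  hit <- abs(records$avg_logFC) > lfc_min & records$p_val_adj < padj_max
  tdeg_genes <- sort(unique(records$gene[hit]))
  list(records = records, tdeg_genes = tdeg_genes,
       skipped_pairs = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Fit smooth spline curves of expression along a continuous axis
#'
#' Gene-wise least-squares regression on a natural cubic spline basis of the
#' time (or pseudotime) coordinate, evaluated on an equally spaced grid.
#' This is the smoothing step that turns per-cell expression into the
#' gene x grid response matrix that kinetic-module clustering consumes.
#'
#' @param expr gene x cell matrix of log-normalized expression.
#' @param time per-cell continuous coordinate (day or pseudotime).
#' @param df spline degrees of freedom (basis columns); must be smaller than
#'   the number of distinct time values.
#' @param n_grid number of evaluation points spanning `range(time)`.
#' @return object of class `smoothed_curves`: `genes`, `grid`, `values`
#'   (gene x grid fitted matrix), `std` (row-standardized copy), `constant`
#'   (flag for constant rows, exempt from standardization),
#'   `time_points` (the distinct input times).
#' @export
smooth_time_curves <- function(expr, time, df = 3L, n_grid = 100L) {
  stopifnot(ncol(expr) == length(time))
  utime <- sort(unique(time))
  if (length(utime) < 3L) stopf("need at least 3 distinct time values")
  if (df >= length(utime))
    stopf("df = %d is unidentifiable with %d distinct time values",
          df, length(utime))
  o <- order(time)
  time <- time[o]
  y <- t(as.matrix(expr[, o, drop = FALSE]))  # cells x genes
  basis <- splines::ns(time, df = df)
  X <- cbind(1, basis)
  coefs <- qr.coef(qr(X), y)
  coefs[is.na(coefs)] <- 0
  grid <- seq(min(time), max(time), length.out = n_grid)
  Xg <- cbind(1, stats::predict(basis, grid))
  fitted <- t(Xg %*% coefs)  # genes x grid
  rownames(fitted) <- rownames(expr)
  stdz <- standardize_rows(fitted)
  structure(list(genes = rownames(expr), grid = grid, values = fitted,
                 std = stdz$std, constant = stdz$constant,
                 time_points = utime, df = df),
            class = "smoothed_curves")
}

#' Cluster smoothed kinetic curves into modules (Ward linkage)
#'
#' Agglomerative hierarchical clustering of the row-standardized fitted
#' curves with Euclidean distance and the ward.D2 convention (distances not
#' pre-squared), cut into `k` modules. On row-standardized curves Euclidean
#' distance is monotone in 1 - Pearson correlation, so modules group genes
#' by kinetic shape. Deterministic given input order; `hclust` ties resolve
#' by merge order.
#'
#' @param curves a [smooth_time_curves()] result.
#' @param k number of modules (default 4).
#' @return object of class `module_assignment`: `modules` (named integer
#'   vector gene -> raw module id), `mean_curves` (k x grid, standardized
#'   scale), `grid`, `time_points`, `shape_labels` (filled by
#'   [label_module_shapes()]).
#' @export
cluster_kinetic_modules <- function(curves, k = 4L) {
  stopifnot(inherits(curves, "smoothed_curves"))
  n <- length(curves$genes)
  if (k > n) stopf("k = %d exceeds the number of genes (%d)", k, n)
  if (k == 1L) {
    cl <- stats::setNames(rep(1L, n), curves$genes)
  } else {
    hc <- stats::hclust(stats::dist(curves$std), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
    names(cl) <- curves$genes
  }
  mean_curves <- do.call(rbind, lapply(seq_len(k), function(j)
    colMeans(curves$std[cl == j, , drop = FALSE])))
  rownames(mean_curves) <- as.character(seq_len(k))
  structure(list(modules = cl, mean_curves = mean_curves, k = k,
                 grid = curves$grid, time_points = curves$time_points,
                 shape_labels = NULL, shape_cor = NULL),
            class = "module_assignment")
}

canonical_shapes <- c("decreasing", "bell", "valley", "increasing")

#' Label kinetic modules by canonical shape and renumber 1-4
#'
#' Correlates each module's mean curve with the four canonical kinetic
#' templates (decreasing, bell, valley, increasing) evaluated on the same
#' grid and solves the 4 x 4 maximum-total-correlation bijective matching.
#' Modules are then renumbered 1-4 in canonical shape order so module ids
#' are comparable across cell types.
#'
#' @param assignment a [cluster_kinetic_modules()] result with k = 4.
#' @param amplitude amplitude used for the reference templates (shape, not
#'   scale, drives the matching since curves are standardized).
#' @return the assignment with `modules` renumbered, `shape_labels` (module
#'   id -> shape) and `shape_cor` (4 x 4 correlation matrix) filled in.
#' @export
label_module_shapes <- function(assignment, amplitude = 4) {
  stopifnot(inherits(assignment, "module_assignment"))
  if (assignment$k != 4L)
    stopf("shape labeling requires exactly 4 modules (got k = %d)",
          assignment$k)
  if (!all(is.finite(assignment$mean_curves)))
    stopf("non-finite module mean curves")
  grid <- assignment$grid
  tp <- assignment$time_points
  templates <- do.call(rbind, lapply(1:4, function(kk)
    kinetic_template(kk, grid, group = "treated", amplitude = amplitude,
                     days = tp)))
  rownames(templates) <- canonical_shapes
  cormat <- stats::cor(t(assignment$mean_curves), t(templates))
  # bijective matching maximizing total correlation (24 permutations)
  perms <- permutations4()
  totals <- vapply(seq_len(nrow(perms)), function(i)
    sum(cormat[cbind(1:4, perms[i, ])]), numeric(1))
  best <- perms[which.max(totals), ]
  # best[j] = canonical shape index of raw module j; canonical index IS the
  # final module number (1 decreasing .. 4 increasing)
  new_id <- best
  modules <- stats::setNames(new_id[assignment$modules],
                             names(assignment$modules))
  mean_curves <- assignment$mean_curves[order(new_id), , drop = FALSE]
  rownames(mean_curves) <- as.character(1:4)
  assignment$modules <- modules
  assignment$mean_curves <- mean_curves
  assignment$shape_labels <- stats::setNames(canonical_shapes, 1:4)
  assignment$shape_cor <- cormat
  assignment
}

permutations4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4L), ])
  dimnames(p) <- NULL
  p
}

#' Genes sharing a kinetic module across cell types
#'
#' Counts, for every gene, the number of cell types in which it was assigned
#' to `module_id`, and returns genes reaching `min_cell_types` (inclusive),
#' sorted by count descending then gene name. This is the cross-cell-type
#' shared-TDEG rule (e.g. consistently upregulated module-4 genes shared by
#' at least five cell types).
#'
#' @param assignments named list of [label_module_shapes()] results (one per
#'   cell type), or a data.frame with columns `cell_type`, `gene`, `module`.
#' @param module_id module of interest (1-4).
#' @param min_cell_types inclusive threshold on the cell-type count.
#' @return data.frame: `gene`, `n_cell_types`.
#' @export
shared_tdeg_genes <- function(assignments, module_id, min_cell_types) {
  if (!(length(module_id) == 1L && module_id %in% 1:4))
    stopf("unknown module id '%s'", toString(module_id))
  if (is.data.frame(assignments)) {
    df <- assignments
  } else {
    df <- do.call(rbind, lapply(names(assignments), function(ct) {
      a <- assignments[[ct]]
      data.frame(cell_type = ct, gene = names(a$modules),
                 module = as.integer(a$modules), stringsAsFactors = FALSE)
    }))
  }
  df <- df[df$module == module_id, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(gene = character(0), n_cell_types = integer(0)))
  cnt <- tapply(df$cell_type, df$gene, function(x) length(unique(x)))
  out <- data.frame(gene = names(cnt), n_cell_types = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cell_types >= min_cell_types, , drop = FALSE]
  out <- out[order(-out$n_cell_types, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
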