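#' Read gene sets from a GMT file
#'
#' @param path GMT file: tab-separated `name`, `description`, members...
#' @return named list of character vectors (unique members), with the
#'   descriptions as attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-cell gene-set activity by ranking recovery-curve AUC
#'
#' For each cell, genes are ranked by expression (descending, average ranks
#' for ties) and the recovery curve R(x) = number of set members among the
#' top x genes is accumulated up to maxRank = ceiling(top_fraction * G).
#' The score is the recovery-curve area normalized by its maximum possible
#' value, so it lies in \[0, 1\]: 1 when the whole set leads the ranking,
#' 0 when no member appears within maxRank.
#'
#' @param expr gene x cell expression matrix (any monotone scale; the score
#'   is rank-based).
#' @param gene_set character vector of member genes, or a named list of sets.
#' @param top_fraction fraction of the ranking examined (default 0.05).
#' @param ties `"average"` (deterministic, default) or `"random"` (AUCell's
#'   randomized tie-breaking; seed with `set.seed` for reproducibility).
#' @return numeric per-cell score vector for a single set, or a cell x set
#'   matrix for a list of sets.
#' @export
aucell_score <- function(expr, gene_set, top_fraction = 0.05,
                         ties = c("average", "random")) {
  ties <- match.arg(ties)
  if (is.list(gene_set)) {
    out <- vapply(gene_set, function(s)
      aucell_score(expr, s, top_fraction, ties), numeric(ncol(expr)))
    rownames(out) <- colnames(expr)
    return(out)
  }
  expr <- as.matrix(expr)
  G <- nrow(expr)
  members <- intersect(gene_set, rownames(expr))
  if (!length(members)) {
    stopf("no gene-set member found in the universe; missing: %s",
          toString(utils::head(setdiff(gene_set, rownames(expr)), 10)))
  }
  max_rank <- ceiling(top_fraction * G)
  m <- length(members)
  k <- min(m, max_rank)
  denom <- sum(pmin(seq_len(max_rank), k))
  midx <- match(members, rownames(expr))
  tie_method <- if (ties == "average") "average" else "random"
  scores <- vapply(seq_len(ncol(expr)), function(cc) {
    r <- rank(-expr[, cc], ties.method = tie_method)[midx]
    # area under R(x), x = 1..maxRank: each member at rank r contributes
    # one unit for every x >= ceiling(r)
    sum(pmax(0, max_rank - ceiling(r) + 1)) / denom
  }, numeric(1))
  names(scores) <- colnames(expr)
  scores
}

# weighted-KS running sum for one set; metric must be sorted descending
gsea_es <- function(metric_sorted, hit, p = 1) {
  G <- length(metric_sorted)
  m <- sum(hit)
  if (m == 0L || m == G) stopf("gene set must be a proper non-empty subset")
  w <- abs(metric_sorted)^p
  nr <- sum(w[hit])
  steps <- ifelse(hit, if (nr > 0) w / nr else 1 / m, -1 / (G - m))
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

#' Gene-set enrichment by the weighted Kolmogorov-Smirnov statistic
#'
#' Classical two-tailed enrichment: the running sum increments at set hits
#' (weighted by |metric|^p, normalized over hits) and decrements by
#' 1/(G - m) at misses; ES is the extremum. The null distribution comes from
#' gene-label permutations; NES divides ES by the mean |null ES| of matching
#' sign, the nominal p is the sign-matched permutation tail with +1
#' smoothing, and FDR across sets follows the sign-matched NES-ratio
#' convention (for a single set, FDR equals the nominal p).
#'
#' @param metric named numeric vector: the signed ranking metric per gene
#'   (e.g. avg_logFC between arms). Ties order deterministically by name.
#' @param gene_sets named list of character vectors (or one vector).
#' @param p weight exponent (default 1).
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p_val`, `FDR`.
#' @export
gsea_enrichment <- function(metric, gene_sets, p = 1, n_perm = 1000L,
                            seed = 1L) {
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (any(!is.finite(metric))) stopf("ranking metric must be finite")
  o <- order(-metric, names(metric))
  metric_sorted <- metric[o]
  universe <- names(metric_sorted)
  G <- length(universe)

  with_seed(seed, {
    res <- lapply(names(gene_sets), function(nm) {
      members <- intersect(gene_sets[[nm]], universe)
      m <- length(members)
      if (m == 0L) stopf("gene set '%s' has no member in the universe", nm)
      if (m == G) stopf("gene set '%s' equals the whole universe", nm)
      hit <- universe %in% members
      es <- gsea_es(metric_sorted, hit, p)
      null_es <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(G, m)
        h <- logical(G); h[idx] <- TRUE
        gsea_es(metric_sorted, h, p)
      }, numeric(1))
      pos <- null_es[null_es >= 0]
      neg <- null_es[null_es < 0]
      if (es >= 0) {
        nes <- if (length(pos)) es / mean(pos) else NA_real_
        pval <- (1 + sum(pos >= es)) / (length(pos) + 1)
      } else {
        nes <- if (length(neg)) es / mean(abs(neg)) else NA_real_
        pval <- (1 + sum(neg <= es)) / (length(neg) + 1)
      }
      list(set = nm, size = m, ES = es, NES = nes, p_val = pval,
           null_es = null_es)
    })

    # sign-matched NES-ratio FDR across the tested sets
    null_nes_all <- unlist(lapply(res, function(r) {
      pos <- r$null_es[r$null_es >= 0]
      neg <- r$null_es[r$null_es < 0]
      c(if (length(pos)) pos / mean(pos),
        if (length(neg)) neg / mean(abs(neg)))
    }))
    obs_nes <- vapply(res, function(r) r$NES, numeric(1))
    fdr <- vapply(seq_along(res), function(i) {
      nes <- obs_nes[i]
      if (length(res) == 1L) return(res[[i]]$p_val)
      if (!is.finite(nes)) return(NA_real_)
      if (nes >= 0) {
        num_pool <- null_nes_all[null_nes_all >= 0]
        num <- if (length(num_pool)) mean(num_pool >= nes) else 0
        den_pool <- obs_nes[is.finite(obs_nes) & obs_nes >= 0]
        den <- mean(den_pool >= nes)
      } else {
        num_pool <- null_nes_all[null_nes_all < 0]
        num <- if (length(num_pool)) mean(num_pool <= nes) else 0
        den_pool <- obs_nes[is.finite(obs_nes) & obs_nes < 0]
        den <- mean(den_pool <= nes)
      }
      if (den == 0) return(NA_real_)
      min(1, num / den)
    }, numeric(1))

    out <- data.frame(set = vapply(res, `[[`, character(1), "set"),
                      size = vapply(res, `[[`, numeric(1), "size"),
                      ES = vapply(res, `[[`, numeric(1), "ES"),
                      NES = obs_nes,
                      p_val = vapply(res, `[[`, numeric(1), "p_val"),
                      FDR = fdr, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Stratified gene-set score summaries with between-arm tests
#'
#' Summarizes per-cell gene-set scores (median, IQR) within strata defined by
#' metadata columns, and tests vehicle vs treated within each stratum using
#' the same rank-sum engine as the differential expression step.
#'
#' @param scores per-cell score vector (named by cell id) or cell x set
#'   matrix from [aucell_score()].
#' @param meta per-cell data.frame with `cell_id` and `group`.
#' @param set_name which set to summarize when `scores` is a matrix.
#' @param stratify_by metadata columns defining strata (default
#'   `"cell_type"`).
#' @param groups the two arm labels to contrast (reference first).
#' @return data.frame with one row per stratum x arm: `n`, `median`, `IQR`,
#'   and the per-stratum between-arm rank-sum `p_val` (NA, flagged, when an
#'   arm has fewer than 2 cells).
#' @export
score_contrast <- function(scores, meta, set_name = NULL,
                           stratify_by = "cell_type",
                           groups = c("vehicle", "treated")) {
  if (is.matrix(scores)) {
    stopifnot(!is.null(set_name), set_name %in% colnames(scores))
    scores <- scores[, set_name]
  }
  stopifnot(all(stratify_by %in% names(meta)), "group" %in% names(meta))
  s <- scores[match(meta$cell_id, names(scores))]
  strata <- interaction(meta[stratify_by], drop = TRUE, sep = "|")
  rows <- lapply(levels(strata), function(st) {
    in_st <- strata == st
    xs <- lapply(groups, function(g) s[in_st & meta$group == g])
    testable <- all(vapply(xs, length, integer(1)) >= 2L)
    pv <- if (testable) unname(de_test(xs[[2]], xs[[1]])["p_val"]) else NA_real_
    do.call(rbind, lapply(seq_along(groups), function(gi) {
      x <- xs[[gi]]
      data.frame(stratum = st, group = groups[gi], n = length(x),
                 median = if (length(x)) stats::median(x) else NA_real_,
                 IQR = if (length(x)) stats::IQR(x) else NA_real_,
                 p_val = pv, tested = testable, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
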