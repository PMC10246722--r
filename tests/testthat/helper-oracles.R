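# Independent oracles used by unit and acceptance tests. These re-derive
# expected values from first principles and must stay independent of the
# package code paths they check.

# two-sided exact Wilcoxon p by explicit enumeration of every rank
# assignment of group A among the pooled ranks
wilcox_enum_p <- function(xA, xB) {
  nA <- length(xA)
  r <- rank(c(xA, xB))
  obs <- sum(r[seq_len(nA)])
  idx <- utils::combn(length(r), nA)
  sums <- colSums(matrix(sort(r)[idx], nrow = nA))
  min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

# recovery-curve AUC by materializing R(x) step by step
auc_brute <- function(x, members, top_fraction) {
  G <- length(x)
  r <- rank(-x, ties.method = "average")
  max_rank <- ceiling(top_fraction * G)
  k <- min(length(members), max_rank)
  R <- vapply(seq_len(max_rank), function(xx) sum(r[members] <= xx),
              numeric(1))
  sum(R) / sum(pmin(seq_len(max_rank), k))
}

# weighted-KS enrichment score by materializing the full running sum
gsea_brute_es <- function(metric, members, p = 1) {
  o <- order(-metric, names(metric))
  nm <- names(metric)[o]
  w <- abs(metric[o])^p
  hit <- nm %in% members
  nr <- sum(w[hit])
  running <- numeric(length(nm))
  acc <- 0
  for (i in seq_along(nm)) {
    acc <- acc + if (hit[i]) w[i] / nr else -1 / (length(nm) - sum(hit))
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# noiseless synthetic kinetic-shape curves for clustering tests:
# n_per genes per canonical shape, with per-gene amplitude jitter
planted_shape_curves <- function(n_per = 10, days = c(0, 3, 9, 15),
                                 n_cells_per_day = 5, noise_sd = 0,
                                 amp_range = c(3, 5)) {
  day_vec <- rep(days, each = n_cells_per_day)
  genes <- paste0("s", rep(1:4, each = n_per), "_", seq_len(n_per))
  truth <- rep(1:4, each = n_per)
  amps <- stats::runif(length(genes), amp_range[1], amp_range[2])
  expr <- t(vapply(seq_along(genes), function(i)
    kinetic_template(truth[i], day_vec, "treated", amps[i], days = days) +
      stats::rnorm(length(day_vec), sd = noise_sd),
    numeric(length(day_vec))))
  rownames(expr) <- genes
  colnames(expr) <- paste0("c", seq_along(day_vec))
  list(expr = expr, day = day_vec, truth = stats::setNames(truth, genes))
}

# planted single-lineage expression fixture: a latent coordinate t in [0, 1]
# drives n_signal genes linearly; root population = earliest 10% of cells
lineage_fixture <- function(n = 500, G = 100, n_signal = min(30, G),
                            sd = 0.3, seed = 2) {
  set.seed(seed)
  t_true <- sort(runif(n))
  expr <- matrix(rnorm(G * n, sd = sd), G, n,
                 dimnames = list(paste0("g", 1:G), paste0("c", 1:n)))
  for (i in seq_len(n_signal))
    expr[i, ] <- expr[i, ] + (i %% 3 + 1) * t_true
  meta <- data.frame(cell_id = colnames(expr),
                     cell_type = ifelse(t_true < 0.1, "root", "other"),
                     stringsAsFactors = FALSE)
  list(expr = expr, meta = meta, t_true = t_true)
}

# small all-in-one crosstalk fixture: two arms, two cell types, one
# ligand/receptor pair; `boost` applies to the treated arm only
crosstalk_fixture <- function(n_per_type = 100, boost = TRUE) {
  arms <- c("vehicle", "treated")
  cells <- as.vector(outer(seq_len(2 * n_per_type), arms,
                           function(i, a) paste0(a, "_c", i)))
  meta <- data.frame(
    cell_id = cells,
    group = rep(arms, each = 2 * n_per_type),
    cell_type = rep(rep(c("A", "B"), each = n_per_type), 2),
    stringsAsFactors = FALSE)
  lig <- rep(0.1, nrow(meta))
  rec <- rep(0.1, nrow(meta))
  if (boost) {
    lig[meta$group == "treated" & meta$cell_type == "A"] <- 2
    rec[meta$group == "treated" & meta$cell_type == "B"] <- 2
  }
  expr <- rbind(Lig1 = lig, Rec1 = rec)
  colnames(expr) <- meta$cell_id
  list(expr = expr, meta = meta,
       pairs = data.frame(ligand = "Lig1", receptor = "Rec1",
                          pathway = "toy", stringsAsFactors = FALSE))
}
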