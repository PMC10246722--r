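#' Tukey trimean
#'
#' Robust location summary (Q1 + 2 * median + Q3) / 4 with
#' linear-interpolation (type-7) quantiles; the expression summary behind
#' ligand-receptor scoring.
#'
#' @param values non-empty numeric vector.
#' @return numeric scalar.
#' @export
trimean <- function(values) {
  if (!length(values)) stopf("trimean of an empty vector is undefined")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  (q[1] + 2 * q[2] + q[3]) / 4
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns `ligand`, `receptor` and optionally
#'   `pathway`.
#' @return data.frame of pairs.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("ligand", "receptor") %in% names(df)))
  if (!"pathway" %in% names(df)) df$pathway <- NA_character_
  df
}

#' Score one ligand-receptor pair between two cell types
#'
#' Interaction score = trimean(ligand expression in sender cells) x
#' trimean(receptor expression in receiver cells), within one treatment arm.
#' Significance comes from `n_perm` shuffles of the cell-type labels within
#' the arm (expression stays fixed), p = (1 + #\{null >= observed\}) /
#' (n_perm + 1); a pair is significant iff p < `alpha` and the score is
#' positive.
#'
#' @param lognorm gene x cell log-normalized matrix.
#' @param meta per-cell data.frame with `cell_id`, `cell_type`, `group`.
#' @param ligand,receptor gene names; unresolvable genes raise an error (the
#'   batch driver [crosstalk_events()] skips them with a warning instead).
#' @param sender,receiver cell-type labels.
#' @param group treatment arm to score.
#' @param n_perm label permutations (default 100).
#' @param seed RNG seed.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: arm, sender, receiver, ligand, receptor,
#'   score, p_val, significant.
#' @export
lr_score_test <- function(lognorm, meta, ligand, receptor, sender, receiver,
                          group, n_perm = 100L, seed = 1L, alpha = 0.05) {
  if (!ligand %in% rownames(lognorm) || !receptor %in% rownames(lognorm))
    stopf("pair genes absent from the matrix: %s",
          toString(setdiff(c(ligand, receptor), rownames(lognorm))))
  arm <- meta[meta$group == group, , drop = FALSE]
  if (!any(arm$cell_type == sender) || !any(arm$cell_type == receiver))
    stopf("sender/receiver population empty within arm '%s'", group)
  lig <- as.numeric(lognorm[ligand, match(arm$cell_id, colnames(lognorm))])
  rec <- as.numeric(lognorm[receptor, match(arm$cell_id, colnames(lognorm))])
  labels <- arm$cell_type
  obs <- trimean(lig[labels == sender]) * trimean(rec[labels == receiver])
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- sample(labels)
    trimean(lig[perm == sender]) * trimean(rec[perm == receiver])
  }, numeric(1)))
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  data.frame(arm = group, sender = sender, receiver = receiver,
             ligand = ligand, receptor = receptor, score = obs, p_val = p,
             significant = p < alpha & obs > 0, stringsAsFactors = FALSE)
}

#' Score all ligand-receptor pairs across sender/receiver types in one arm
#'
#' Batch driver over [lr_score_test()]: every pair from the table, every
#' ordered (sender, receiver) combination. Pairs whose genes are missing
#' from the matrix are skipped with a warning and listed in the
#' `"skipped_pairs"` attribute.
#'
#' @param lognorm,meta as in [lr_score_test()].
#' @param pairs data.frame with `ligand`, `receptor` (see
#'   [read_lr_pairs()]).
#' @param group arm label.
#' @param senders,receivers cell types to use (default: all present in the
#'   arm).
#' @param n_perm,seed,alpha as in [lr_score_test()].
#' @return data.frame of per-(pair, sender, receiver) results.
#' @export
crosstalk_events <- function(lognorm, meta, pairs, group,
                             senders = NULL, receivers = NULL,
                             n_perm = 100L, seed = 1L, alpha = 0.05) {
  arm_types <- sort(unique(meta$cell_type[meta$group == group]))
  senders <- senders %||% arm_types
  receivers <- receivers %||% arm_types
  ok <- pairs$ligand %in% rownames(lognorm) &
    pairs$receptor %in% rownames(lognorm)
  if (any(!ok))
    warnf("%d pair(s) skipped: gene(s) not in the matrix", sum(!ok))
  kept <- pairs[ok, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(kept))) {
    for (sd in senders) {
      for (rc in receivers) {
        # one deterministic sub-seed per (pair, sender, receiver) so results
        # do not depend on evaluation order
        sub_seed <- (seed + 7919L * i + 131L * match(sd, senders) +
                       match(rc, receivers)) %% .Machine$integer.max
        out[[length(out) + 1L]] <- lr_score_test(
          lognorm, meta, kept$ligand[i], kept$receptor[i], sd, rc, group,
          n_perm = n_perm, seed = sub_seed, alpha = alpha)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(arm = character(0), sender = character(0),
               receiver = character(0), ligand = character(0),
               receptor = character(0), score = numeric(0),
               p_val = numeric(0), significant = logical(0))
  attr(res, "skipped_pairs") <- pairs[!ok, , drop = FALSE]
  res
}

#' Differential ligand-receptor event counts between arms
#'
#' For every (sender, receiver) pair of cell types, the signed difference in
#' the number of significant ligand-receptor events: treated minus vehicle.
#' Also returns the union per-pair table with per-arm significance flags for
#' downstream (e.g. Sankey) export.
#'
#' @param results_vehicle,results_treated [crosstalk_events()] outputs for
#'   the two arms; they must cover identical pair and cell-type universes.
#' @return list: `delta` (data.frame `sender`, `receiver`, `n_vehicle`,
#'   `n_treated`, `delta`), `pairs` (union table).
#' @export
interaction_delta <- function(results_vehicle, results_treated) {
  key <- function(r) paste(r$sender, r$receiver, r$ligand, r$receptor,
                           sep = "\r")
  if (!setequal(key(results_vehicle), key(results_treated)))
    stopf("the two arms were not scored on the same pair/cell-type universe")
  v <- results_vehicle[order(key(results_vehicle)), , drop = FALSE]
  t2 <- results_treated[order(key(results_treated)), , drop = FALSE]
  pairs <- data.frame(sender = v$sender, receiver = v$receiver,
                      ligand = v$ligand, receptor = v$receptor,
                      score_vehicle = v$score, p_vehicle = v$p_val,
                      sig_vehicle = v$significant,
                      score_treated = t2$score, p_treated = t2$p_val,
                      sig_treated = t2$significant, stringsAsFactors = FALSE)
  combos <- unique(pairs[, c("sender", "receiver")])
  delta <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- pairs$sender == combos$sender[i] &
      pairs$receiver == combos$receiver[i]
    nv <- sum(pairs$sig_vehicle[sel])
    nt <- sum(pairs$sig_treated[sel])
    data.frame(sender = combos$sender[i], receiver = combos$receiver[i],
               n_vehicle = nv, n_treated = nt, delta = nt - nv,
               stringsAsFactors = FALSE)
  }))
  delta <- delta[order(delta$sender, delta$receiver), , drop = FALSE]
  rownames(delta) <- NULL
  list(delta = delta, pairs = pairs)
}
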