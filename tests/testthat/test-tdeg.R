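test_that("de_test handles identity, exact and fold-change worked cases", {
  x <- c(1.2, 0.8, 1.5, 2.0)
  same <- de_test(x, x)
  expect_equal(unname(same["avg_logFC"]), 0)
  expect_equal(unname(same["p_val"]), 1)

  res <- de_test(c(1.2, 0.8, 1.5, 2.0), c(0.1, 0.0, 0.3, 0.2))
  expect_equal(unname(res["p_val"]), 2 / 70)

  lfc <- de_test(rep(log(2), 6), rep(0, 6))
  expect_equal(unname(lfc["avg_logFC"]), log(2))
})

test_that("exact de_test p equals enumeration over all rank assignments", {
  set.seed(101)
  for (i in 1:60) {
    nA <- sample(2:7, 1); nB <- sample(2:7, 1)
    repeat {  # tie-free draws
      xA <- round(rnorm(nA), 6); xB <- round(rnorm(nB), 6)
      if (!anyDuplicated(c(xA, xB))) break
    }
    expect_equal(unname(de_test(xA, xB)["p_val"]), wilcox_enum_p(xA, xB),
                 tolerance = 1e-12)
  }
})

test_that("approximate de_test matches wilcox.test with corrections", {
  set.seed(55)
  for (i in 1:20) {
    xA <- round(rnorm(15), 1)  # rounding induces ties
    xB <- round(rnorm(12, 0.5), 1)
    ours <- unname(de_test(xA, xB)["p_val"])
    ref <- suppressWarnings(stats::wilcox.test(xA, xB, exact = FALSE,
                                               correct = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("bh_adjust reproduces hand-computed and reference adjustments", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
})

test_that("bh_adjust is monotone-dominating and permutation-equivariant", {
  set.seed(14)
  p <- runif(100)
  a <- bh_adjust(p)
  expect_true(all(a >= p) && all(a <= 1))
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), a[perm])
})

test_that("TDEG thresholds are strict on both fold change and adjusted p", {
  # gene "near": avg_logFC exactly 0.20 with a tiny p; gene "big": clear hit
  n <- 20
  near_hi <- rep(log1p(exp(0.2) - 1), n)   # mean(expm1)+1 = e^0.2
  big_hi <- rep(log1p(exp(2) - 1), n)
  expr <- rbind(near = c(near_hi, rep(0, n)), big = c(big_hi, rep(0, n)))
  colnames(expr) <- paste0("c", seq_len(2 * n))
  meta <- data.frame(cell_id = colnames(expr), day = rep(c(3, 0), each = n))
  res <- find_time_degs(expr, meta, lfc_min = 0.25, padj_max = 0.05)
  near_rec <- res$records[res$records$gene == "near", ]
  expect_equal(near_rec$avg_logFC, 0.2, tolerance = 1e-12)
  expect_lt(near_rec$p_val_adj, 0.05)
  expect_false("near" %in% res$tdeg_genes)  # |lfc| = 0.20 is not > 0.25
  expect_true("big" %in% res$tdeg_genes)
})

test_that("planted module-4 genes are detected as TDEGs", {
  cfg <- sim_config(n_genes = 300, n_cell_types = 1, cells_per_condition = 50,
                    genes_per_module = c(0, 0, 0, 20), markers_per_type = 0,
                    amplitude = 4, seed = 17)
  ds <- simulate_dataset(cfg)
  ln <- normalize_log(ds$counts)
  res <- find_time_degs(ln, ds$meta, cell_type = "T1", group = "treated")
  planted <- names(ds$truth$gene_module)
  expect_gte(mean(planted %in% res$tdeg_genes), 0.9)
  # constant genes never enter
  expect_false(any(grepl("^BG", res$tdeg_genes)) &&
                 length(res$tdeg_genes) == 0)
})

test_that("day pairs lacking cells are skipped with a warning", {
  expr <- matrix(rexp(40), 2, 20,
                 dimnames = list(c("g1", "g2"), paste0("c", 1:20)))
  meta <- data.frame(cell_id = colnames(expr),
                     day = c(rep(0, 9), rep(3, 9), rep(9, 2)))
  # both pairs involving day 9 (0-9 and 3-9) are skipped, one warning each
  expect_warning(
    expect_warning(res <- find_time_degs(expr, meta, min_cells = 3),
                   "skipped"),
    "skipped")
  expect_true(all(res$records$dayA != 9))
  expect_equal(nrow(res$skipped_pairs), 2)
})

test_that("spline smoothing reproduces constants and straight lines", {
  day <- rep(c(0, 3, 9, 15), each = 5)
  expr <- rbind(flat = rep(2.5, 20), line = 0.3 * day + 1)
  colnames(expr) <- paste0("c", 1:20)
  cur <- smooth_time_curves(expr, day, df = 3, n_grid = 50)
  expect_equal(unname(cur$values["flat", ]), rep(2.5, 50), tolerance = 1e-8)
  expect_equal(unname(cur$values["line", ]), 0.3 * cur$grid + 1,
               tolerance = 1e-6)
  expect_true(cur$constant["flat"])
  # standardized rows: mean ~ 0, sd ~ 1 for non-constant genes
  expect_lt(abs(mean(cur$std["line", ])), 1e-8)
  expect_lt(abs(stats::sd(cur$std["line", ]) - 1), 1e-6)
})

test_that("a noiseless bell-shaped gene peaks strictly inside the window", {
  day <- rep(c(0, 3, 9, 15), each = 5)
  expr <- matrix(kinetic_template(2, day, "treated", 4), 1, length(day),
                 dimnames = list("bell", paste0("c", seq_along(day))))
  cur <- smooth_time_curves(expr, day)
  peak <- which.max(cur$values["bell", ])
  expect_gt(peak, 1)
  expect_lt(peak, length(cur$grid))
})

test_that("smoothing rejects an unidentifiable basis", {
  day <- rep(c(0, 3, 9), each = 4)
  expr <- matrix(rnorm(12), 1, 12,
                 dimnames = list("g", paste0("c", 1:12)))
  expect_error(smooth_time_curves(expr, day, df = 3), "unidentifiable")
})

test_that("module clustering recovers planted shapes", {
  set.seed(23)
  fx <- planted_shape_curves(n_per = 10, noise_sd = 0)
  cur <- smooth_time_curves(fx$expr, fx$day)
  asg <- cluster_kinetic_modules(cur, k = 4)
  expect_equal(adjusted_rand_index(asg$modules, fx$truth[names(asg$modules)]),
               1.0)
  # degenerate cut: one module holds everything
  one <- cluster_kinetic_modules(cur, k = 1)
  expect_true(all(one$modules == 1))
  expect_error(cluster_kinetic_modules(cur, k = 100), "exceeds")
})

test_that("module clustering tolerates noise (mean ARI over seeds)", {
  aris <- vapply(1:5, function(s) {
    set.seed(s)
    fx <- planted_shape_curves(n_per = 10, noise_sd = 0.3)
    cur <- smooth_time_curves(fx$expr, fx$day)
    asg <- cluster_kinetic_modules(cur, k = 4)
    adjusted_rand_index(asg$modules, fx$truth[names(asg$modules)])
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("clustering is invariant to gene order up to relabeling", {
  set.seed(29)
  fx <- planted_shape_curves(n_per = 8, noise_sd = 0.2)
  cur1 <- smooth_time_curves(fx$expr, fx$day)
  perm <- sample(nrow(fx$expr))
  cur2 <- smooth_time_curves(fx$expr[perm, ], fx$day)
  a1 <- cluster_kinetic_modules(cur1, 4)$modules
  a2 <- cluster_kinetic_modules(cur2, 4)$modules
  expect_equal(adjusted_rand_index(a1, a2[names(a1)]), 1.0)
})

test_that("shape labeling maps modules to canonical kinetics bijectively", {
  set.seed(37)
  fx <- planted_shape_curves(n_per = 10, noise_sd = 0)
  cur <- smooth_time_curves(fx$expr, fx$day)
  asg <- label_module_shapes(cluster_kinetic_modules(cur, k = 4))
  expect_identical(unname(asg$shape_labels),
                   c("decreasing", "bell", "valley", "increasing"))
  # after renumbering, module ids equal the planted shape ids exactly
  expect_identical(unname(asg$modules), unname(fx$truth[names(asg$modules)]))
  expect_identical(dim(asg$shape_cor), c(4L, 4L))
})

test_that("synthetic mean curves get the expected individual shape labels", {
  grid <- seq(0, 15, length.out = 100)
  curves <- rbind(kinetic_template(4, grid, "treated", 4),      # increasing
                  kinetic_template(3, grid, "treated", 4),      # valley
                  kinetic_template(1, grid, "treated", 4),      # decreasing
                  kinetic_template(2, grid, "treated", 4))      # bell
  rownames(curves) <- paste0("m", 1:4)
  asg <- structure(list(modules = stats::setNames(1:4, paste0("m", 1:4)),
                        mean_curves = curves, k = 4L, grid = grid,
                        time_points = c(0, 3, 9, 15)),
                   class = "module_assignment")
  lab <- label_module_shapes(asg)
  expect_identical(unname(lab$modules),
                   c(4L, 3L, 1L, 2L))  # increasing, valley, decreasing, bell
})

test_that("shared-gene counting honors the inclusive threshold", {
  df <- data.frame(
    cell_type = c(paste0("ct", 1:5), paste0("ct", 1:4)),
    gene = c(rep("gA", 5), rep("gB", 4)),
    module = 4L)
  res <- shared_tdeg_genes(df, 4, min_cell_types = 5)
  expect_identical(res$gene, "gA")
  expect_identical(res$n_cell_types, 5L)
  expect_error(shared_tdeg_genes(df, 9, 2), "module id")
})

test_that("shared-gene counting equals a brute-force nested loop", {
  set.seed(41)
  tab <- data.frame(
    cell_type = sample(paste0("ct", 1:10), 2000, replace = TRUE),
    gene = sample(paste0("g", 1:200), 2000, replace = TRUE),
    module = sample(1:4, 2000, replace = TRUE))
  tab <- unique(tab)
  for (mod in c(1, 4)) {
    for (thr in c(2, 5)) {
      res <- shared_tdeg_genes(tab, mod, thr)
      brute <- integer(0)
      for (g in unique(tab$gene)) {
        cnt <- 0L
        for (ct in unique(tab$cell_type)) {
          if (any(tab$gene == g & tab$cell_type == ct & tab$module == mod))
            cnt <- cnt + 1L
        }
        if (cnt >= thr) brute[g] <- cnt
      }
      expect_setequal(res$gene, names(brute))
      expect_identical(res$n_cell_types,
                       unname(brute[res$gene]))
      # ordering: count descending, then gene name
      expect_identical(order(-res$n_cell_types, res$gene),
                       seq_len(nrow(res)))
    }
  }
})

test_that("every TDEG lands in exactly one module of its cell type", {
  cfg <- sim_config(n_genes = 400, n_cell_types = 1, cells_per_condition = 40,
                    genes_per_module = 25, markers_per_type = 0, seed = 43)
  ds <- simulate_dataset(cfg)
  ln <- normalize_log(ds$counts)
  res <- find_time_degs(ln, ds$meta, cell_type = "T1", group = "treated")
  sub <- ds$meta$cell_type == "T1" & ds$meta$group == "treated"
  cur <- smooth_time_curves(ln[res$tdeg_genes, ds$meta$cell_id[sub]],
                            ds$meta$day[sub])
  asg <- cluster_kinetic_modules(cur, 4)
  expect_setequal(names(asg$modules), res$tdeg_genes)
  expect_false(anyDuplicated(names(asg$modules)) > 0)
  expect_true(all(asg$modules %in% 1:4))
})
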