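test_that("pseudotime tracks a planted lineage and anchors at the root", {
  fx <- lineage_fixture()
  pt <- pseudotime_order(fx$expr, fx$meta, "root", genes_use = "all")
  expect_gte(abs(cor(pt$cells$pseudotime, fx$t_true, method = "spearman")),
             0.9)
  root_pt <- pt$cells$pseudotime[fx$meta$cell_type == "root"]
  expect_equal(min(root_pt), 0)
  expect_equal(range(pt$cells$pseudotime), c(0, 1))
})

test_that("a duplicated root cell sits at pseudotime zero too", {
  fx <- lineage_fixture(n = 80, G = 20, n_signal = 10)
  pt0 <- pseudotime_order(fx$expr, fx$meta, "root", genes_use = "all",
                          k_nn = 5)
  dup <- fx$expr[, pt0$root_cell, drop = FALSE]
  colnames(dup) <- "dup_root"
  expr <- cbind(fx$expr, dup)
  meta <- rbind(fx$meta, data.frame(cell_id = "dup_root",
                                    cell_type = "root"))
  pt <- pseudotime_order(expr, meta, "root", genes_use = "all", k_nn = 5)
  expect_equal(pt$cells$pseudotime[pt$cells$cell_id == "dup_root"], 0)
})

test_that("pseudotime is invariant under rigid rotation of the data", {
  fx <- lineage_fixture(n = 60, G = 6, n_signal = 4, sd = 0.2, seed = 5)
  pt1 <- pseudotime_order(fx$expr, fx$meta, "root", d = 6, k_nn = 5,
                          genes_use = "all")
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))  # random orthogonal map
  rot <- Q %*% fx$expr
  dimnames(rot) <- dimnames(fx$expr)
  pt2 <- pseudotime_order(rot, fx$meta, "root", d = 6, k_nn = 5,
                          genes_use = "all")
  expect_equal(pt2$cells$pseudotime, pt1$cells$pseudotime, tolerance = 1e-8)
})

test_that("missing root labels are rejected", {
  fx <- lineage_fixture(n = 40, G = 10, n_signal = 5)
  expect_error(pseudotime_order(fx$expr, fx$meta, "bulge"), "root label")
})

test_that("expression ratio is the fraction of expressing cells", {
  expect_identical(expression_ratio(c(0, 0, 0)), 0)
  expect_identical(expression_ratio(c(2, 1, 5)), 1)
  expect_identical(expression_ratio(c(0, 0, 1, 3, 0)), 0.4)
  expect_error(expression_ratio(numeric(0)), "at least one")
})

test_that("spline LRT is non-negative and powerful on monotone signal", {
  set.seed(61)
  pt <- sort(runif(300))
  y_sig <- rnbinom(300, mu = 2 * 4^pt, size = 2)
  res <- spline_lrt(y_sig, pt)
  expect_gte(res[["lrt_stat"]], 0)
  expect_lt(res[["p_val"]], 1e-4)
  for (i in 1:10) {
    y <- rnbinom(100, mu = 2, size = 2)
    expect_gte(spline_lrt(y, runif(100))[["lrt_stat"]], 0)
  }
  expect_identical(spline_lrt(rep(3L, 50), runif(50))[["p_val"]], 1)
})

test_that("wave-DEG selection keeps at most n_top, ranked by q then LRT", {
  set.seed(71)
  n <- 1500
  recs <- data.frame(gene = paste0("g", 1:n),
                     lrt_stat = runif(n, 1, 50),
                     p_val = runif(n, 0, 1e-4),
                     q_value = runif(n, 0, 0.04),
                     expression_ratio = runif(n, 0.2, 1))
  ln <- matrix(rnorm(n * 30), n, 30,
               dimnames = list(recs$gene, paste0("c", 1:30)))
  ptv <- seq(0, 1, length.out = 30)
  sel <- wave_deg_modules(recs, ln, ptv, n_top = 1000, k = 3)
  expect_identical(nrow(sel$selection), 1000L)
  expected <- with(recs[order(recs$q_value, -recs$lrt_stat, recs$gene), ],
                   head(gene, 1000))
  expect_identical(sel$selection$gene, expected)

  # fewer significant than n_top: all kept
  recs400 <- recs[1:400, ]
  sel400 <- wave_deg_modules(recs400, ln[1:400, ], ptv, n_top = 1000, k = 3)
  expect_identical(nrow(sel400$selection), 400L)

  # selection is a pure function of the records, not their order
  perm <- sample(n)
  sel_perm <- wave_deg_modules(recs[perm, ], ln, ptv, n_top = 1000, k = 3)
  expect_identical(sel_perm$selection$gene, sel$selection$gene)
})

test_that("filters drop genes failing q or expression-ratio cutoffs", {
  recs <- data.frame(gene = c("a", "b", "c"),
                     lrt_stat = c(10, 10, 10),
                     p_val = c(1e-5, 1e-5, 0.5),
                     q_value = c(0.01, 0.01, 0.6),
                     expression_ratio = c(0.5, 0.05, 0.5))
  ln <- matrix(rnorm(30), 3, 10,
               dimnames = list(c("a", "b", "c"), paste0("c", 1:10)))
  sel <- wave_deg_modules(recs, ln, seq(0, 1, length.out = 10), k = 1)
  expect_identical(sel$selection$gene, "a")  # b: ratio 5% <= 10%; c: q >= 0.05
  expect_warning(
    wave_deg_modules(recs[3, ], ln[3, , drop = FALSE],
                     seq(0, 1, length.out = 10)),
    "no gene")
})

test_that("planted expression waves are recovered and numbered by peak", {
  set.seed(83)
  n_cells <- 120
  ptv <- seq(0, 1, length.out = n_cells)
  bump <- function(center) exp(-(ptv - center)^2 / (2 * 0.12^2))
  waves <- c(early = 0.05, mid = 0.5, late = 0.95)
  genes <- paste0(rep(names(waves), each = 10), "_", 1:10)
  ln <- t(vapply(rep(waves, each = 10), bump, numeric(n_cells))) *
    runif(30, 2, 4)
  rownames(ln) <- genes
  colnames(ln) <- paste0("c", seq_len(n_cells))
  recs <- data.frame(gene = genes, lrt_stat = 10, p_val = 1e-6,
                     q_value = 1e-5, expression_ratio = 1)
  sel <- wave_deg_modules(recs, ln, ptv, n_top = 1000, k = 3)
  truth <- rep(1:3, each = 10)
  names(truth) <- genes
  got <- sel$selection$wave_cluster[match(genes, sel$selection$gene)]
  expect_equal(adjusted_rand_index(got, truth), 1.0)
  expect_identical(got, unname(truth))  # numbering follows peak order
})

test_that("binned composition respects bin edges and reports empty bins", {
  # proportions sum to one in non-empty bins
  set.seed(91)
  ptv <- runif(200)
  lab <- sample(c("A", "B", "C"), 200, replace = TRUE)
  comp <- binned_composition(ptv, lab, n_bins = 20)
  sums <- tapply(comp$proportion[comp$n > 0], comp$bin[comp$n > 0], sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # perfect split at 0.5
  ptv2 <- c(seq(0, 0.49, length.out = 50), seq(0.5, 0.99, length.out = 50))
  lab2 <- rep(c("A", "B"), each = 50)
  comp2 <- binned_composition(ptv2, lab2, n_bins = 20)
  filled <- comp2[comp2$n > 0, ]
  expect_true(all(filled$label[filled$bin <= 10] == "A"))
  expect_true(all(filled$label[filled$bin > 10] == "B"))
  expect_true(all(filled$proportion == 1))

  # all cells at pseudotime 0: first bin holds everything
  comp3 <- binned_composition(rep(0, 7), rep("A", 7), n_bins = 20)
  expect_identical(comp3$n[comp3$bin == 1], 7L)
  expect_true(all(comp3$n[comp3$bin > 1] == 0L))
  expect_error(binned_composition(0.5, "A", n_bins = 0), "n_bins")
})
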