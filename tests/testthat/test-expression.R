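test_that("replicate averaging is the arithmetic mean per individual", {
  expr <- rbind(expr_rows("g1", "i1", 10, 1L), expr_rows("g1", "i1", 12, 2L),
                expr_rows("g1", "i1", 14, 3L), expr_rows("g2", "i1", 7, 1L))
  avg <- average_replicates(expr)
  expect_equal(avg$fpkm[avg$gene_id == "g1"], 12)
  expect_equal(avg$fpkm[avg$gene_id == "g2"], 7)
  expect_error(average_replicates(expr[0, ]), "empty")
})

test_that("technical replicates at CV 0.1 correlate strongly, matching the QC regime", {
  cfg <- small_config(replicate_cv = 0.1, n_autosomal_genes = 300L)
  cat <- simulate_catalog(cfg)
  panel <- simulate_mutant_panel(cat, cfg)
  expr <- simulate_expression(cat, panel$truth, cfg)
  sub <- expr[expr$individual == "CTRL1", ]
  r1 <- sub$fpkm[sub$replicate == 1][order(sub$gene_id[sub$replicate == 1])]
  r2 <- sub$fpkm[sub$replicate == 2][order(sub$gene_id[sub$replicate == 2])]
  expect_gt(stats::cor(r1, r2), 0.8)
})

test_that("categories partition genes and follow the deleted-Y definition", {
  cat <- manual_catalog(data.frame(
    gene_id = c("s1", "s2", "a1"), class = c("sex_linked", "sex_linked",
                                             "autosomal"),
    x_id = c("s1X", "s2X", NA), y_id = c("s1Y", "s2Y", NA),
    stringsAsFactors = FALSE))
  cats <- categorize("mut", deleted_y = "s1", cat)
  lab <- setNames(cats$category, cats$gene_id)
  expect_identical(lab[["s1X"]], "X_del")
  expect_identical(lab[["s2X"]], "X_nondel")
  expect_identical(lab[["s2Y"]], "Y_nondel")
  expect_identical(lab[["a1"]], "Aut")
  expect_false("s1Y" %in% cats$gene_id)  # deleted Y copies excluded
  # X_del and X_nondel partition the X gene set
  x <- cats[cats$category %in% c("X_del", "X_nondel"), ]
  expect_setequal(x$gene_id, c("s1X", "s2X"))
  # autosomal deletion mode
  cats2 <- categorize("mut", character(0), cat, hemizygous = "a1")
  expect_identical(cats2$category[cats2$gene_id == "a1"], "A_del")
  expect_error(categorize("mut", "ghost", cat), "ghost")
})

test_that("relative expression divides replicate-averaged values and drops low controls", {
  avg <- rbind(expr_rows("g1", "mut", 18), expr_rows("g2", "mut", 4),
               expr_rows("g1", "ctrl", 10), expr_rows("g2", "ctrl", 0.1))
  rel <- relative_expression(avg, list(mut = "ctrl"), floor = 0.5)
  expect_equal(rel$ratio[rel$gene_id == "g1"], 1.8)
  expect_false("g2" %in% rel$gene_id)
  expect_identical(attr(rel, "excluded")[["mut"]], 1L)
  expect_error(relative_expression(avg, list(ghost = "ctrl")), "ghost")
})

test_that("exact rank-sum p values match brute-force enumeration", {
  res <- category_test(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$p, enum_wilcox_p(c(1, 2), c(3, 4))$p)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- sample(seq(0.1, 10, by = 0.1), n)
    y <- sample(setdiff(seq(0.1, 10, by = 0.1), x), m)
    got <- category_test(x, y)
    oracle <- enum_wilcox_p(x, y)
    expect_true(got$exact)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
    expect_equal(got$W, oracle$W)
  }
})

test_that("identical groups give p = 1 and one-group mode tests a null median", {
  expect_equal(category_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  one <- category_test(c(0.48, 0.51, 0.52, 0.47, 0.55), null_value = 0.5)
  expect_gt(one$p, 0.05)
  shifted <- category_test(seq(0.9, 1.4, by = 0.05), null_value = 0.5)
  expect_lt(shifted$p, 0.01)
  expect_error(category_test(numeric(0), c(1, 2)), "empty")
  expect_error(category_test(c(1, 2)), "null_value")
})

test_that("stratification bins follow the dS and degeneration boundaries", {
  cat <- manual_catalog(data.frame(
    gene_id = c("s1", "s2", "s3", "s4"), class = "sex_linked",
    x_id = paste0("s", 1:4, "X"), y_id = paste0("s", 1:4, "Y"),
    dS = c(0.02, 0.05, 0.2, NA), yx_ratio = c(0.8, 0.3, 0.1, 0.71),
    stringsAsFactors = FALSE))
  ds <- stratify(cat, "dS")
  expect_identical(unname(ds[c("s1", "s2", "s3")]),
                   c("low", "intermediate", "high"))
  expect_identical(attr(ds, "unbinned"), "s4")
  deg <- stratify(cat, "degeneration")
  expect_identical(unname(deg[c("s1", "s2", "s3", "s4")]),
                   c("non_degenerate", "partially_degenerated",
                     "highly_degenerate", "non_degenerate"))
})

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  # step-up on (0.01, 0.02, 0.03, 0.04), m = 4: cummin from the top is 0.04
  expr <- do.call(rbind, lapply(1:4, function(i) {
    rbind(expr_rows(paste0("g", i), "mut", c(10, 11, 12) + i, 1:3),
          expr_rows(paste0("g", i), "ctrl", c(10, 10, 10), 1:3))
  }))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))  # frozen hand computation: min_i p_(i)*m/i
  de <- per_gene_de_test(expr, "mut", "ctrl")
  expect_true(all(de$q >= de$p, na.rm = TRUE))
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
})

test_that("identical replicate sets give t = 0 and p = 1; short sets are skipped", {
  expr <- rbind(expr_rows("g1", "mut", c(5, 5, 5), 1:3),
                expr_rows("g1", "ctrl", c(5, 5, 5), 1:3),
                expr_rows("g2", "mut", 7, 1L),
                expr_rows("g2", "ctrl", c(5, 6), 1:2))
  de <- per_gene_de_test(expr, "mut", "ctrl")
  expect_equal(de$t[de$gene_id == "g1"], 0)
  expect_equal(de$p[de$gene_id == "g1"], 1)
  expect_identical(attr(de, "skipped"), "g2")
})

test_that("under the null few genes pass the FDR threshold", {
  cfg <- small_config(n_factor_mutants = 0L, n_hemizygous = 0L)
  cat <- simulate_catalog(cfg)
  panel <- simulate_mutant_panel(cat, cfg)
  expr <- simulate_expression(cat, panel$truth, cfg)
  muts <- setdiff(unique(expr$individual),
                  grep("^CTRL", unique(expr$individual), value = TRUE))
  de <- per_gene_de_test(expr, muts[1], "CTRL1")
  expect_lte(mean(de$q < 0.05, na.rm = TRUE), 0.05)
})

test_that("PCA separates planted effect groups and collapses identical mutants", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:40)
  groups <- rep(1:3, each = 4)
  rel <- do.call(rbind, lapply(seq_along(groups), function(i) {
    shift <- c(1, 2, 0.5)[groups[i]]
    data.frame(gene_id = genes, mutant_id = sprintf("m%02d", i),
               ratio = shift * exp(rnorm(40, 0, 0.05)),
               stringsAsFactors = FALSE)
  }))
  res <- pca_mutants(rel, k = 3)
  tab <- table(res$clusters, groups[match(names(res$clusters),
                                          sprintf("m%02d", seq_along(groups)))])
  expect_true(all(rowSums(tab > 0) == 1))  # clusters align with truth
  # identical mutants: all scores collapse to zero
  rel0 <- rel
  rel0$ratio <- rep(rel$ratio[rel$mutant_id == "m01"],
                    times = length(groups))
  res0 <- pca_mutants(rel0, k = 3)
  expect_lt(max(abs(res0$scores)), 1e-8)
  expect_error(pca_mutants(rel[rel$mutant_id %in% c("m01", "m02"), ]),
               "three")
})

test_that("density peaks detect the planted bimodality and its absence", {
  cfg <- small_config(compensated_fraction = 0.5, compensation_fold = 2,
                      n_sexlinked_genes = 200L)
  cat <- simulate_catalog(cfg)
  panel <- simulate_mutant_panel(cat, cfg)
  expr <- simulate_expression(cat, panel$truth, cfg)
  avg <- average_replicates(expr)
  controls <- grep("^CTRL", unique(expr$individual), value = TRUE)
  idc_mut <- names(panel$truth$idc_triggered)[panel$truth$idc_triggered][1]
  rel <- relative_expression(avg, setNames(list(controls), idc_mut))
  sl <- cat$genes[cat$genes$class == "sex_linked", ]
  del_x <- sl$x_id[sl$gene_id %in% panel$truth$deleted_y_genes[[idc_mut]]]
  ratios <- rel$ratio[rel$gene_id %in% del_x]
  peaks <- density_peaks(ratios)
  expect_length(peaks, 2L)
  expect_equal(peaks[1], 1, tolerance = 0.1)
  expect_equal(peaks[2], 2, tolerance = 0.15)
  # no compensation: a single peak at 1
  cfg0 <- small_config(compensated_fraction = 0)
  cat0 <- simulate_catalog(cfg0)
  panel0 <- simulate_mutant_panel(cat0, cfg0)
  expr0 <- simulate_expression(cat0, panel0$truth, cfg0)
  avg0 <- average_replicates(expr0)
  idc0 <- names(panel0$truth$idc_triggered)[panel0$truth$idc_triggered][1]
  rel0 <- relative_expression(avg0, setNames(list(controls), idc0))
  sl0 <- cat0$genes[cat0$genes$class == "sex_linked", ]
  p0 <- density_peaks(rel0$ratio[rel0$gene_id %in% sl0$x_id])
  expect_length(p0, 1L)
  expect_equal(p0, 1, tolerance = 0.1)
  expect_error(density_peaks(c(1, 2)), "10")
  expect_error(density_peaks(rnorm(20), bandwidth = -1), "bandwidth")
})
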