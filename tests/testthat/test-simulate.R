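test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(n_autosomal_genes = 0), "n_autosomal_genes")
  expect_error(simulation_config(factor_interval = c(0, 5)), "factor_interval")
  expect_error(simulation_config(n_markers = 10, factor_interval = c(5, 12)),
               "factor_interval")
  expect_error(simulation_config(compensated_fraction = 1.2),
               "compensated_fraction")
  expect_error(simulation_config(compensation_fold = 0), "compensation_fold")
})

test_that("generators are bit-identical for identical seed and config", {
  cfg <- small_config(seed = 7)
  a <- simulate_all(cfg)
  b <- simulate_all(cfg)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expression, b$expression)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$allelic, b$allelic)
  expect_identical(a$methylation, b$methylation)
  c <- simulate_catalog(small_config(seed = 8))
  expect_false(identical(a$catalog$genes, c$genes))
})

test_that("catalog populates all dS and degeneration bins and handles no sex-linked genes", {
  cat <- simulate_catalog(small_config())
  sl <- cat$genes[cat$genes$class == "sex_linked", ]
  expect_true(all(table(cut(sl$dS, c(0, 0.04, 0.08, Inf))) > 0))
  expect_true(all(table(cut(sl$yx_ratio, c(0, 0.3, 0.7, Inf))) > 0))
  expect_true(all(cat$genes$length_bp > 0))
  aut_only <- simulate_catalog(small_config(n_sexlinked_genes = 0))
  expect_identical(unique(aut_only$genes$class), "autosomal")
})

test_that("mutant deletions are contiguous runs and the IDC flag marks exactly the factor deleters", {
  cfg <- small_config(n_mutants = 40, n_factor_mutants = 5)
  cat <- simulate_catalog(cfg)
  panel <- simulate_mutant_panel(cat, cfg)
  calls <- panel$matrix$calls[, panel$truth$marker_order]
  for (m in rownames(calls)) {
    runs <- rle(calls[m, ])
    expect_lte(sum(runs$values == 0L), 2L)
  }
  expect_identical(sum(panel$truth$idc_triggered), 5L)
  fi <- cfg$factor_interval
  covers <- vapply(panel$truth$deletion_runs, function(rs) {
    any(vapply(rs, function(r) r[1] <= fi[2] && r[2] >= fi[1], logical(1)))
  }, logical(1))
  expect_identical(unname(covers), unname(panel$truth$idc_triggered))
})

test_that("a single planted run yields the expected presence row", {
  cfg <- small_config(n_markers = 10, n_mutants = 1, n_factor_mutants = 1,
                      factor_interval = c(4L, 6L))
  cat <- simulate_catalog(cfg)
  panel <- simulate_mutant_panel(cat, cfg)
  row <- panel$matrix$calls[1, panel$truth$marker_order]
  del <- which(row == 0L)
  expect_true(all(diff(del) == 1L))              # contiguous
  expect_true(all(c(4L, 5L, 6L) %in% del))       # covers the factor interval
})

test_that("deleted Y gametologs have exactly zero FPKM in every replicate", {
  cfg <- small_config()
  cat <- simulate_catalog(cfg)
  panel <- simulate_mutant_panel(cat, cfg)
  expr <- simulate_expression(cat, panel$truth, cfg)
  sl <- cat$genes[cat$genes$class == "sex_linked", ]
  for (m in intersect(names(panel$truth$deleted_y_genes),
                      unique(expr$individual))) {
    del_y <- sl$y_id[sl$gene_id %in% panel$truth$deleted_y_genes[[m]]]
    vals <- expr$fpkm[expr$individual == m & expr$gene_id %in% del_y]
    if (length(vals)) expect_true(all(vals == 0))
    surv <- expr$fpkm[expr$individual == m &
                        expr$gene_id %in% setdiff(sl$y_id, del_y)]
    expect_true(all(surv > 0))
  }
})

test_that("coverage ratios reflect copy number and scale with depth", {
  cfg <- small_config(n_hemizygous = 30, depth = 200)
  cat <- simulate_catalog(cfg)
  panel <- simulate_mutant_panel(cat, cfg)
  cov <- simulate_coverage(cat, panel$truth, cfg)
  mut <- cov[cov$sample_id == "mutant", ]
  ctl <- cov[cov$sample_id == "control", ]
  hemi <- mut$gene_id %in% panel$truth$hemizygous_genes
  expect_lt(abs(mean(mut$mapped_reads[hemi]) / mean(ctl$mapped_reads[hemi]) -
                  0.5), 0.05)
  expect_lt(abs(mean(mut$mapped_reads[!hemi]) / mean(ctl$mapped_reads[!hemi]) -
                  1), 0.08)
  cov2 <- simulate_coverage(cat, panel$truth,
                            small_config(n_hemizygous = 30, depth = 400))
  expect_equal(mean(cov2$mapped_reads) / mean(cov$mapped_reads), 2,
               tolerance = 0.05)
})

test_that("allelic counts conserve totals, honour the progeny design and the planted bias", {
  cfg <- small_config(cross_progeny = c(male = 20L, female = 32L))
  cat <- simulate_catalog(cfg)
  al <- simulate_allelic_counts(cat, cfg)
  expect_identical(length(unique(al$individual_id)), 52L)
  expect_identical(sum(tapply(al$sex, al$individual_id, unique) == "male"), 20L)
  # both origins present for every (gene, individual)
  n_orig <- tapply(al$origin, paste(al$gene_id, al$individual_id),
                   function(o) length(unique(o)))
  expect_true(all(n_orig == 2L))
  aut <- al[al$gene_id %in%
              cat$genes$gene_id[cat$genes$class == "autosomal"], ]
  pooled <- sum(aut$reads[aut$origin == "maternal"]) /
    sum(aut$reads[aut$origin == "paternal"])
  expect_equal(pooled, 1, tolerance = 0.05)
  cfg2 <- small_config(imprinting_bias = 2)
  al2 <- simulate_allelic_counts(simulate_catalog(cfg2), cfg2)
  cat2 <- simulate_catalog(cfg2)
  slx <- al2[al2$gene_id %in%
               cat2$genes$gene_id[cat2$genes$class == "sex_linked"] &
               al2$sex == "female", ]
  pooled2 <- sum(slx$reads[slx$origin == "maternal"]) /
    sum(slx$reads[slx$origin == "paternal"])
  expect_equal(pooled2, 2, tolerance = 0.1)
})

test_that("methylation counts recover the per-context rates", {
  cfg <- small_config(methylation_rates = c(CpG = 0.8, CHG = 0.02, CHH = 0.02))
  cat <- simulate_catalog(cfg)
  meth <- simulate_methylation(cat, cfg)
  for (ctx in c("CpG", "CHG", "CHH")) {
    sub <- meth[meth$context == ctx, ]
    obs <- sum(sub$meth_count) / sum(sub$meth_count + sub$unmeth_count)
    expect_lt(abs(obs - cfg$methylation_rates[[ctx]]), 0.005)
  }
})

test_that("simulate_all writes the full set of plain-text artifacts", {
  dir <- withr::local_tempdir()
  simulate_all(small_config(), dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "catalog.tsv", "marker_matrix.tsv", "expression.tsv", "coverage.tsv",
    "allelic_counts.tsv", "methylation.tsv", "truth.json")))))
  expr <- read_tsv_file(file.path(dir, "expression.tsv"),
                        required_cols = c("gene_id", "individual", "fpkm"))
  expect_true(all(expr$fpkm >= 0))
})
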