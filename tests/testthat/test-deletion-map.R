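test_that("markers with identical patterns are grouped into virtual markers", {
  calls <- cbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 1L, 0L, 0L),
                 c = c(0L, 0L, 1L, 1L), d = c(0L, 0L, 1L, 1L))
  rownames(calls) <- paste0("m", 1:4)
  mm <- marker_matrix(calls)
  vms <- cluster_markers(mm, k = 2)
  expect_length(vms, 2L)
  members <- lapply(vms, `[[`, "members")
  expect_setequal(vapply(members, length, integer(1)), c(2L, 2L))
  expect_true(any(vapply(members, setequal, logical(1), c("a", "b"))))
  # k equal to the number of distinct patterns is pure identity grouping
  vms2 <- cluster_markers(mm, k = 2)
  expect_identical(lapply(vms, `[[`, "members"), lapply(vms2, `[[`, "members"))
  expect_error(cluster_markers(mm, k = 5), "exceeds")
  expect_error(cluster_markers(mm, k = 3), "distinct patterns")
})

test_that("a study-sized panel clusters into the requested 14 virtual markers", {
  cfg <- small_config(n_markers = 163L, n_mutants = 101L, n_autosomal_genes = 5L,
                      n_sexlinked_genes = 0L, n_hemizygous = 0L,
                      factor_interval = c(60L, 72L))
  panel <- simulate_mutant_panel(simulate_catalog(cfg), cfg)
  expect_identical(dim(panel$matrix$calls), c(101L, 163L))
  vms <- cluster_markers(panel$matrix, k = 14)
  expect_length(vms, 14L)
  expect_setequal(unlist(lapply(vms, `[[`, "members")),
                  panel$matrix$marker_ids)
})

test_that("a marker with only missing calls is rejected by name", {
  calls <- cbind(a = c(1L, 0L), bad = c(NA_integer_, NA_integer_))
  rownames(calls) <- c("m1", "m2")
  expect_error(marker_matrix(calls), "bad")
})

test_that("breakpoint counting matches direct transition counts and bridges missing calls", {
  expect_identical(breakpoint_count(matrix(c(1L, 0L, 1L, 0L), 1)), 3L)
  expect_identical(breakpoint_count(matrix(1L, 3, 5)), 0L)
  expect_identical(breakpoint_count(matrix(c(1L, NA, 0L), 1)), 1L)
  expect_identical(breakpoint_count(matrix(c(1L, NA, 1L), 1)), 0L)
  expect_error(breakpoint_count(matrix(1L, 1, 1)), "two")
})

test_that("breakpoint count is invariant under order reversal", {
  set.seed(42)
  for (i in 1:20) {
    pat <- random_patterns(6, 7)
    pat[sample(length(pat), 4)] <- NA
    if (any(colSums(!is.na(pat)) == 0)) next
    expect_identical(breakpoint_count(pat),
                     breakpoint_count(pat[, rev(seq_len(ncol(pat)))]))
  }
})

test_that("a single deletion is placed contiguously with minimal breakpoints", {
  # one mutant deleting markers {B, D}: any optimal order makes them adjacent
  pat <- cbind(A = 1L, B = 0L, C = 1L, D = 0L, E = 1L)
  pat <- rbind(pat, pat * 0L + 1L)  # second mutant, all present
  rownames(pat) <- c("m1", "m2")
  map <- order_markers(as_virtuals(pat), method = "exhaustive")
  ord <- map$marker_order
  # free ends: the deleted pair sits at a map end, costing one breakpoint
  expect_identical(map$total_breakpoints, 1L)
  expect_identical(abs(diff(match(c("B", "D"), ord))), 1L)
  expect_true(any(c("B", "D") %in% ord[c(1, length(ord))]))
  # deletion touching an end costs a single breakpoint
  pat2 <- matrix(c(0L, 1L, 1L), 1, dimnames = list("m1", c("A", "B", "C")))
  map2 <- order_markers(as_virtuals(pat2), method = "exhaustive")
  expect_identical(map2$total_breakpoints, 1L)
})

test_that("heuristic ordering matches the exhaustive optimum on random instances", {
  set.seed(11)
  for (i in 1:30) {
    m <- sample(4:7, 1)
    pat <- random_patterns(sample(3:6, 1), m)
    vms <- as_virtuals(pat)
    ex <- order_markers(vms, method = "exhaustive")
    he <- order_markers(vms, method = "heuristic")
    expect_identical(he$total_breakpoints, ex$total_breakpoints)
    expect_identical(ex$total_breakpoints, enum_order_oracle(pat))
  }
})

test_that("exhaustive ordering above the cap errors and suggests the heuristic", {
  pat <- random_patterns(3, 6)
  expect_error(order_markers(as_virtuals(pat), method = "exhaustive", cap = 4),
               "heuristic")
})

test_that("the planted order is recovered up to reversal on a distinguishing panel", {
  # staggered overlapping deletions separate every adjacent marker pair
  n <- 8
  pat <- t(vapply(seq_len(n - 1), function(i) {
    v <- rep(1L, n); v[1:i] <- 0L; v
  }, integer(n)))
  dimnames(pat) <- list(sprintf("m%d", seq_len(n - 1)),
                        sprintf("T%02d", seq_len(n)))
  shuffled <- pat[, sample(n)]
  map <- order_markers(as_virtuals(shuffled), method = "exhaustive")
  recovered <- map$marker_order
  truth <- colnames(pat)
  expect_true(identical(recovered, truth) ||
                identical(recovered, rev(truth)))
  expect_identical(map$alternative_optima, 1L)
})

test_that("within-cluster refinement flags uninformative markers and orders informative ones", {
  cfg <- small_config(n_markers = 24L, n_mutants = 15L, n_sexlinked_genes = 0L,
                      n_autosomal_genes = 5L, n_hemizygous = 0L,
                      factor_interval = c(8L, 10L))
  panel <- simulate_mutant_panel(simulate_catalog(cfg), cfg)
  map <- build_deletion_map(panel$matrix, k = 8)
  expect_setequal(map$marker_order, panel$matrix$marker_ids)
  # refinement never worsens the raw-matrix objective of the unrefined map
  vms <- cluster_markers(panel$matrix, k = 8)
  coarse <- order_markers(vms)
  raw_before <- breakpoint_count(
    panel$matrix$calls[, coarse$marker_order, drop = FALSE])
  expect_lte(map$total_breakpoints, raw_before)
  # clusters of identical patterns are flagged uninformative
  sizes <- lengths(map$within_cluster_orders)
  tbl <- map_as_table(map)
  expect_identical(nrow(tbl), 24L)
  expect_true(is.logical(tbl$uninformative))
})

test_that("map objective is bounded below by unavoidable per-mutant transitions", {
  cfg <- small_config(n_markers = 20L, n_mutants = 10L, n_sexlinked_genes = 0L,
                      n_autosomal_genes = 5L, n_hemizygous = 0L,
                      factor_interval = c(5L, 7L))
  panel <- simulate_mutant_panel(simulate_catalog(cfg), cfg)
  map <- build_deletion_map(panel$matrix, k = 6)
  # each mutant with at least one deletion (not spanning everything)
  # needs at least one transition in any order
  lower <- sum(apply(panel$matrix$calls, 1, function(v) {
    any(v == 0L, na.rm = TRUE) && any(v == 1L, na.rm = TRUE)
  }))
  expect_gte(map$total_breakpoints, lower)
})
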