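# Shared fixtures and independent oracles for the test suite.

# Small, fast simulation configuration used by several tests.
small_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed, n_autosomal_genes = 60L, n_sexlinked_genes = 60L,
    n_markers = 30L, n_mutants = 20L, factor_interval = c(10L, 14L),
    n_factor_mutants = 3L, n_expression_mutants = 8L, n_hemizygous = 15L,
    cross_progeny = c(male = 6L, female = 8L), allelic_depth = 50
  )
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# Hand-built catalog for unit tests that need full control of annotation.
manual_catalog <- function(genes) {
  defaults <- data.frame(
    gene_id = genes$gene_id, class = genes$class,
    x_id = if ("x_id" %in% names(genes)) genes$x_id else NA_character_,
    y_id = if ("y_id" %in% names(genes)) genes$y_id else NA_character_,
    linkage_group = if ("linkage_group" %in% names(genes)) {
      genes$linkage_group
    } else ifelse(genes$class == "autosomal", "LG1", "XY"),
    map_pos = if ("map_pos" %in% names(genes)) genes$map_pos else NA_real_,
    length_bp = if ("length_bp" %in% names(genes)) genes$length_bp else 1000L,
    dS = if ("dS" %in% names(genes)) genes$dS else NA_real_,
    yx_ratio = if ("yx_ratio" %in% names(genes)) genes$yx_ratio else NA_real_,
    marker_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  structure(list(genes = defaults,
                 markers = data.frame(marker_id = character(0),
                                      true_pos = integer(0)),
                 config = NULL),
            class = "gene_catalog")
}

# Long expression rows for one gene copy across individuals/replicates.
expr_rows <- function(gene_id, individual, fpkm, replicate = 1L) {
  data.frame(gene_id = gene_id, individual = individual,
             replicate = replicate,
             sample_id = paste0(individual, "_r", replicate),
             tissue = "leaf", fpkm = fpkm, stringsAsFactors = FALSE)
}

# Brute-force exact two-sided rank-sum p value by enumerating every
# assignment of ranks to the first group. Independent of stats::wilcox.test.
enum_wilcox_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  pl <- mean(ws <= w_obs)
  pu <- mean(ws >= w_obs)
  list(W = w_obs, p = min(1, 2 * min(pl, pu)))
}

# Brute-force marker-order oracle: enumerate every permutation and count
# breakpoints directly on the pattern matrix (mutants x markers).
enum_order_oracle <- function(pat) {
  m <- ncol(pat)
  count_bp <- function(cols) {
    tot <- 0L
    for (i in seq_len(nrow(pat))) {
      v <- pat[i, cols]
      v <- v[!is.na(v)]
      if (length(v) > 1) tot <- tot + sum(diff(v) != 0)
    }
    tot
  }
  best <- Inf
  rec <- function(prefix, rest) {
    if (!length(rest)) {
      b <- count_bp(prefix)
      if (b < best) best <<- b
      return(invisible())
    }
    for (r in rest) rec(c(prefix, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(m))
  best
}

# Random binary pattern matrix whose columns are the markers.
random_patterns <- function(n_mutants, n_markers) {
  matrix(sample(0:1, n_mutants * n_markers, replace = TRUE),
         nrow = n_mutants,
         dimnames = list(sprintf("mut%02d", seq_len(n_mutants)),
                         sprintf("mk%02d", seq_len(n_markers))))
}

as_virtuals <- function(pat) {
  structure(lapply(seq_len(ncol(pat)), function(j) {
    list(members = colnames(pat)[j], pattern = pat[, j])
  }), class = "virtual_markers")
}
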