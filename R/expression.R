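# Relative-expression dosage-compensation statistics: replicate averaging,
# per-mutant gene categories, mutant/control ratios under a phenotype-
# matched pairing, category-level rank tests, dS/degeneration
# stratification, per-gene differential tests with FDR control, PCA of
# mutant profiles, and kernel-density peak detection for bimodality.

#' Average technical replicates
#'
#' Arithmetic mean FPKM per gene, individual and tissue.
#'
#' @param table Long expression table with columns `gene_id`, `individual`,
#'   `fpkm` and optionally `tissue`.
#' @return Data frame `gene_id`, `individual`, `tissue`, `fpkm`.
#' @export
average_replicates <- function(table) {
  if (!nrow(table)) stop("empty expression table", call. = FALSE)
  if (is.null(table$tissue)) table$tissue <- "leaf"
  out <- stats::aggregate(fpkm ~ gene_id + individual + tissue, data = table,
                          FUN = mean)
  out[order(out$gene_id, out$individual), , drop = FALSE]
}

#' Assign a gene category for one mutant
#'
#' Sex-linked genes split into `X_del` (Y gametolog deleted in this mutant)
#' and `X_nondel`; surviving Y gametologs are `Y_nondel` (deleted Y copies
#' are excluded from ratio analysis); autosomal genes are `Aut`, or
#' `A_del`/`A_nondel` when a hemizygous gene set is supplied.
#'
#' @param mutant_id Mutant identifier.
#' @param deleted_y Character vector of gametolog pair ids whose Y copy is
#'   deleted in this mutant (e.g. from [deleted_set()]).
#' @param catalog A `gene_catalog`.
#' @param hemizygous Optional character vector of autosomal gene ids inside
#'   a heterozygous deletion carried by this mutant.
#' @return Data frame `gene_id` (expression-table id), `pair_id`,
#'   `category`.
#' @export
categorize <- function(mutant_id, deleted_y, catalog, hemizygous = NULL) {
  genes <- catalog$genes
  unknown <- setdiff(deleted_y, genes$gene_id)
  if (length(unknown)) {
    stop("gene(s) absent from catalog: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sl <- genes[genes$class == "sex_linked", , drop = FALSE]
  aut <- genes[genes$class == "autosomal", , drop = FALSE]
  del <- sl$gene_id %in% deleted_y
  rows <- list(
    data.frame(gene_id = sl$x_id, pair_id = sl$gene_id,
               category = ifelse(del, "X_del", "X_nondel"),
               stringsAsFactors = FALSE),
    data.frame(gene_id = sl$y_id[!del], pair_id = sl$gene_id[!del],
               category = "Y_nondel", stringsAsFactors = FALSE)
  )
  if (is.null(hemizygous)) {
    rows <- c(rows, list(data.frame(gene_id = aut$gene_id,
                                    pair_id = aut$gene_id,
                                    category = "Aut",
                                    stringsAsFactors = FALSE)))
  } else {
    rows <- c(rows, list(data.frame(
      gene_id = aut$gene_id, pair_id = aut$gene_id,
      category = ifelse(aut$gene_id %in% hemizygous, "A_del", "A_nondel"),
      stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  out$mutant_id <- mutant_id
  rownames(out) <- NULL
  out
}

#' Per-gene mutant/control expression ratios
#'
#' Computes replicate-averaged mutant/control FPKM ratios under a pairing
#' that maps every mutant to its phenotype-matched control individual (or
#' to a pool of controls, averaged). Genes whose control value is below
#' `floor` are dropped; the number dropped per mutant is attached as the
#' `"excluded"` attribute.
#'
#' @param avg Replicate-averaged expression from [average_replicates()].
#' @param pairing Named list or character vector: names are mutant ids,
#'   values the control individual id(s) for that mutant.
#' @param floor Control FPKM below which a ratio is undefined (default 0.5).
#' @param tissue Tissue to analyse (default `"leaf"`).
#' @return Data frame `gene_id`, `mutant_id`, `control`, `ratio`.
#' @export
relative_expression <- function(avg, pairing, floor = 0.5, tissue = "leaf") {
  avg <- avg[avg$tissue == tissue, , drop = FALSE]
  pairing <- as.list(pairing)
  missing_mut <- setdiff(names(pairing), unique(avg$individual))
  if (length(missing_mut)) {
    stop("unpaired or absent mutant(s): ",
         paste(missing_mut, collapse = ", "), call. = FALSE)
  }
  res <- list()
  excluded <- integer(0)
  for (m in names(pairing)) {
    ctrl_ids <- pairing[[m]]
    mut <- avg[avg$individual == m, , drop = FALSE]
    ctl <- avg[avg$individual %in% ctrl_ids, , drop = FALSE]
    ctl_mean <- tapply(ctl$fpkm, ctl$gene_id, mean)
    cv <- ctl_mean[mut$gene_id]
    ok <- !is.na(cv) & cv >= floor
    excluded[m] <- sum(!ok)
    res[[m]] <- data.frame(gene_id = mut$gene_id[ok], mutant_id = m,
                           control = paste(ctrl_ids, collapse = "+"),
                           ratio = mut$fpkm[ok] / cv[ok],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Rank test of a ratio category
#'
#' Two-sample mode compares two ratio sets with the two-sided Wilcoxon rank
#' sum test (exact when both groups have at most `exact_max` values and the
#' pooled data carry no ties; normal approximation with continuity and tie
#' correction otherwise). One-group mode tests the median against
#' `null_value` with the Wilcoxon signed-rank test.
#'
#' @param ratios_a Numeric vector.
#' @param ratios_b Second sample, or `NULL` for one-group mode.
#' @param null_value Null median for one-group mode.
#' @param exact_max Largest group size for which the exact distribution is
#'   used (default 25).
#' @return List with `n_a`, `n_b`, `W` (rank-sum or signed-rank statistic),
#'   `p`, `exact`.
#' @export
category_test <- function(ratios_a, ratios_b = NULL, null_value = NULL,
                          exact_max = 25L) {
  if (!length(ratios_a)) stop("empty group", call. = FALSE)
  if (!is.null(ratios_b)) {
    if (!length(ratios_b)) stop("empty group", call. = FALSE)
    ties <- any(duplicated(c(ratios_a, ratios_b)))
    exact <- min(length(ratios_a), length(ratios_b)) <= exact_max && !ties
    ht <- stats::wilcox.test(ratios_a, ratios_b, exact = exact,
                             correct = TRUE, alternative = "two.sided")
    list(n_a = length(ratios_a), n_b = length(ratios_b),
         W = unname(ht$statistic), p = ht$p.value, exact = exact)
  } else {
    if (is.null(null_value)) {
      stop("supply ratios_b or null_value", call. = FALSE)
    }
    x <- ratios_a[ratios_a != null_value]
    ties <- any(duplicated(abs(x - null_value)))
    exact <- length(x) <= 50L && !ties
    ht <- stats::wilcox.test(ratios_a, mu = null_value, exact = exact,
                             correct = TRUE, alternative = "two.sided")
    list(n_a = length(ratios_a), n_b = 0L,
         W = unname(ht$statistic), p = ht$p.value, exact = exact)
  }
}

#' Summarize ratio categories for one mutant
#'
#' Produces a category summary table (median, SD, n) for the mutant's
#' ratios, with a two-sided rank-sum test of each X/Y category against the
#' autosomal category of the same mutant.
#'
#' @param rel Relative-expression table for one mutant, joined with a
#'   `category` column (as from [categorize()]).
#' @return Data frame: `mutant_id`, `category`, `n_genes`, `median_ratio`,
#'   `sd_ratio`, `W`, `p_vs_autosomal`.
#' @export
summarize_categories <- function(rel) {
  stopifnot(all(c("mutant_id", "category", "ratio") %in% names(rel)))
  out <- list()
  for (m in unique(rel$mutant_id)) {
    sub <- rel[rel$mutant_id == m, , drop = FALSE]
    aut <- sub$ratio[sub$category %in% c("Aut", "A_nondel")]
    for (cat in unique(sub$category)) {
      r <- sub$ratio[sub$category == cat]
      W <- NA_real_; p <- NA_real_
      if (length(r) >= 2 && length(aut) >= 2 &&
          !cat %in% c("Aut", "A_nondel")) {
        tst <- category_test(r, aut)
        W <- tst$W; p <- tst$p
      }
      out[[length(out) + 1L]] <- data.frame(
        mutant_id = m, category = cat, n_genes = length(r),
        median_ratio = stats::median(r), sd_ratio = stats::sd(r),
        W = W, p_vs_autosomal = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stratify sex-linked genes by divergence or Y degeneration
#'
#' dS bins follow the three age strata: low (dS < 0.04), intermediate
#' (0.04 to 0.08) and high (dS > 0.08); degeneration bins follow the
#' control Yc/Xc expression ratio: highly degenerate (< 0.3), partially
#' degenerated (0.3 to 0.7) and non-degenerate (> 0.7). Interval bounds of
#' the middle bin are closed. Genes missing the stratifying value get `NA`
#' and are counted in the `"unbinned"` attribute.
#'
#' @param catalog A `gene_catalog`.
#' @param by `"dS"` or `"degeneration"`.
#' @return Named character vector of bin labels for the sex-linked genes.
#' @export
stratify <- function(catalog, by = c("dS", "degeneration")) {
  by <- match.arg(by)
  sl <- catalog$genes[catalog$genes$class == "sex_linked", , drop = FALSE]
  v <- if (by == "dS") sl$dS else sl$yx_ratio
  labels <- if (by == "dS") {
    ifelse(v < 0.04, "low", ifelse(v <= 0.08, "intermediate", "high"))
  } else {
    ifelse(v < 0.3, "highly_degenerate",
           ifelse(v <= 0.7, "partially_degenerated", "non_degenerate"))
  }
  names(labels) <- sl$gene_id
  attr(labels, "unbinned") <- sl$gene_id[is.na(v)]
  labels
}

#' Per-gene differential expression across technical replicates
#'
#' Welch t test per gene between mutant and control replicate FPKM values,
#' Benjamini-Hochberg adjusted across the tested set. Genes with fewer
#' than two replicates on either side are skipped and listed in the
#' `"skipped"` attribute. The output feeds volcano plots (log2 ratio
#' against -log10 adjusted p).
#'
#' @param expression Long expression table.
#' @param mutant,control Individual ids.
#' @return Data frame `gene_id`, `log2_ratio`, `t`, `p`, `q`.
#' @export
per_gene_de_test <- function(expression, mutant, control) {
  mut <- expression[expression$individual == mutant, , drop = FALSE]
  ctl <- expression[expression$individual %in% control, , drop = FALSE]
  genes <- intersect(unique(mut$gene_id), unique(ctl$gene_id))
  res <- vector("list", length(genes))
  skipped <- character(0)
  for (i in seq_along(genes)) {
    g <- genes[i]
    x <- mut$fpkm[mut$gene_id == g]
    y <- ctl$fpkm[ctl$gene_id == g]
    if (length(x) < 2 || length(y) < 2 ||
        (stats::var(x) == 0 && stats::var(y) == 0)) {
      if (length(x) < 2 || length(y) < 2) skipped <- c(skipped, g)
      tval <- if (length(x) >= 2 && length(y) >= 2) 0 else NA_real_
      res[[i]] <- data.frame(gene_id = g,
                             log2_ratio = log2(mean(x) / mean(y)),
                             t = tval, p = if (is.na(tval)) NA_real_ else 1,
                             stringsAsFactors = FALSE)
      next
    }
    ht <- stats::t.test(x, y)
    res[[i]] <- data.frame(gene_id = g,
                           log2_ratio = log2(mean(x) / mean(y)),
                           t = unname(ht$statistic), p = ht$p.value,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  attr(out, "skipped") <- skipped
  out
}

#' Principal components of mutant relative-expression profiles
#'
#' Builds the mutants x genes matrix of log2 ratios (genes observed in
#' every mutant), centres each gene, extracts principal components with
#' [stats::prcomp()], and clusters the mutant scores with k-means.
#'
#' @param rel Relative-expression table (`gene_id`, `mutant_id`, `ratio`).
#' @param k Number of clusters (default 3).
#' @param n_pc Number of component scores returned (default 2).
#' @return List: `scores` (mutants x PCs), `clusters` (named integer),
#'   `var_explained`, `n_genes`.
#' @export
pca_mutants <- function(rel, k = 3L, n_pc = 2L) {
  muts <- unique(rel$mutant_id)
  if (length(muts) < 3L) stop("need at least three mutants", call. = FALSE)
  mat <- tapply(rel$ratio, list(rel$mutant_id, rel$gene_id), mean)
  mat <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
  if (!ncol(mat)) stop("no gene observed in every mutant", call. = FALSE)
  lmat <- log2(mat)
  # drop genes with non-finite log ratios (zero expression in a mutant)
  lmat <- lmat[, apply(is.finite(lmat), 2, all), drop = FALSE]
  pc <- stats::prcomp(lmat, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  k_eff <- min(k, nrow(unique(scores)))
  cl <- stats::kmeans(scores, centers = k_eff, nstart = 10L)
  list(scores = scores,
       clusters = stats::setNames(cl$cluster, rownames(scores)),
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       n_genes = ncol(lmat))
}

#' Locate peaks of a kernel-smoothed ratio density
#'
#' Gaussian kernel density on a fixed grid (Silverman's rule bandwidth by
#' default); local maxima whose density exceeds `prominence` times the
#' global maximum are returned, sorted by location. Used to detect the
#' bimodality of relative-expression distributions.
#'
#' @param ratios Numeric vector (at least 10 values).
#' @param bandwidth Kernel bandwidth; `NULL` for Silverman's rule.
#' @param prominence Fraction of the maximum density a peak must reach
#'   (default 0.1).
#' @return Numeric vector of peak locations.
#' @export
density_peaks <- function(ratios, bandwidth = NULL, prominence = 0.1) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 10L) {
    stop("need at least 10 finite values", call. = FALSE)
  }
  if (!is.null(bandwidth) && bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  d <- stats::density(ratios, bw = bandwidth %||% stats::bw.nrd0(ratios),
                      n = 512L)
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], FALSE)
  is_peak <- is_peak & y > prominence * max(y)
  sort(d$x[is_peak])
}
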