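# Bisulfite methylation comparison between mutants and control: coverage
# filtering (per-site minimum and per-gene average), per-gene methylation
# percentages by sequence context, and mutant/control ratio tests.

METH_CONTEXTS <- c("CpG", "CHG", "CHH")

#' Filter methylation sites by coverage
#'
#' Removes sites with coverage (methylated + unmethylated reads) below
#' `min_site_cov`, then removes entirely any gene whose mean site coverage
#' (before site filtering, per sample and region) is below
#' `min_gene_avg_cov`.
#'
#' @param table Methylation table with columns `gene_id`, `sample_id`,
#'   `region`, `meth_count`, `unmeth_count`.
#' @param min_site_cov Minimum per-site coverage (default 5; a site at
#'   exactly the minimum is retained).
#' @param min_gene_avg_cov Minimum per-gene mean site coverage (default 3).
#' @return The filtered table.
#' @export
filter_sites <- function(table, min_site_cov = 5L, min_gene_avg_cov = 3) {
  cov <- table$meth_count + table$unmeth_count
  key <- paste(table$gene_id, table$sample_id, table$region)
  gene_mean <- tapply(cov, key, mean)
  keep_gene <- gene_mean[key] >= min_gene_avg_cov
  keep <- cov >= min_site_cov & keep_gene
  table[keep, , drop = FALSE]
}

#' Per-gene methylation percentage by context
#'
#' 100 * sum(methylated) / sum(coverage) over a gene's retained sites of
#' one context. Gene/context combinations with zero retained coverage are
#' reported with `NA` percentage.
#'
#' @param table A (filtered) methylation table.
#' @param context Optional subset of contexts (default all of CpG, CHG,
#'   CHH); an unknown label is an error.
#' @return Data frame `sample_id`, `gene_id`, `region`, `context`, `pct`,
#'   `coverage`.
#' @export
methylation_percentage <- function(table, context = METH_CONTEXTS) {
  bad <- setdiff(context, METH_CONTEXTS)
  if (length(bad)) {
    stop("unknown context label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tb <- table[table$context %in% context, , drop = FALSE]
  if (!nrow(tb)) {
    return(data.frame(sample_id = character(0), gene_id = character(0),
                      region = character(0), context = character(0),
                      pct = numeric(0), coverage = numeric(0)))
  }
  agg <- stats::aggregate(cbind(meth_count, unmeth_count) ~
                            sample_id + gene_id + region + context,
                          data = tb, FUN = sum)
  cov <- agg$meth_count + agg$unmeth_count
  data.frame(sample_id = agg$sample_id, gene_id = agg$gene_id,
             region = agg$region, context = agg$context,
             pct = ifelse(cov > 0, 100 * agg$meth_count / cov, NA_real_),
             coverage = cov, stringsAsFactors = FALSE)
}

#' Compare methylation between mutant and control
#'
#' Joins per-gene methylation percentages of a mutant and a control sample
#' by gene, region and context, computes mutant/control ratios (undefined
#' when the control percentage is 0; such genes are counted separately),
#' and tests the mutant and control percentage distributions against each
#' other with the two-sided Wilcoxon rank sum test, per context and
#' region. When `categories` is supplied (gene -> category, e.g. X_del /
#' X_nondel / Aut), summaries are additionally split by category. A
#' one-group signed-rank test of the ratios against 1 is also reported.
#'
#' @param pct Percentage table from [methylation_percentage()] containing
#'   both samples.
#' @param mutant,control Sample ids.
#' @param categories Optional named character vector gene_id -> category.
#' @return List: `ratios` (per-gene data frame), `tests` (per
#'   context/region/category data frame), `n_undefined`.
#' @export
compare_methylation <- function(pct, mutant = "mutant", control = "control",
                                categories = NULL) {
  mu <- pct[pct$sample_id == mutant, , drop = FALSE]
  co <- pct[pct$sample_id == control, , drop = FALSE]
  key <- function(d) paste(d$gene_id, d$region, d$context, sep = "|")
  shared <- intersect(key(mu), key(co))
  if (!length(shared)) stop("disjoint gene sets between samples", call. = FALSE)
  mu <- mu[match(shared, key(mu)), , drop = FALSE]
  co <- co[match(shared, key(co)), , drop = FALSE]
  ratio <- ifelse(!is.na(co$pct) & co$pct > 0, mu$pct / co$pct, NA_real_)
  ratios <- data.frame(gene_id = mu$gene_id, region = mu$region,
                       context = mu$context, pct_mutant = mu$pct,
                       pct_control = co$pct, ratio = ratio,
                       stringsAsFactors = FALSE)
  if (!is.null(categories)) {
    ratios$category <- unname(categories[ratios$gene_id])
  } else {
    ratios$category <- "all"
  }
  tests <- list()
  for (ctx in unique(ratios$context)) {
    for (reg in unique(ratios$region)) {
      for (cat in unique(ratios$category)) {
        sub <- ratios[ratios$context == ctx & ratios$region == reg &
                        (is.na(ratios$category) | ratios$category == cat), ,
                      drop = FALSE]
        sub <- sub[!is.na(sub$category) & sub$category == cat, , drop = FALSE]
        ok_pair <- !is.na(sub$pct_mutant) & !is.na(sub$pct_control)
        if (sum(ok_pair) < 2) next
        rs <- category_test(sub$pct_mutant[ok_pair], sub$pct_control[ok_pair])
        r <- sub$ratio[!is.na(sub$ratio)]
        sr_p <- if (length(r) >= 2 && any(r != 1)) {
          category_test(r, null_value = 1)$p
        } else NA_real_
        tests[[length(tests) + 1L]] <- data.frame(
          context = ctx, region = reg, category = cat,
          n_genes = sum(ok_pair), median_ratio = stats::median(r),
          p_rank_sum = rs$p, p_ratio_vs_1 = sr_p,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ratios = ratios,
       tests = if (length(tests)) do.call(rbind, tests) else NULL,
       n_undefined = sum(is.na(ratio)))
}
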