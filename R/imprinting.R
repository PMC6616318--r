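# Parent-of-origin allele-specific expression analysis for a genetic
# cross: per-origin allelic expression E = r / (n * l), origin-by-sex
# averages per gene, Y/X degeneration binning, and signed-rank tests of
# maternal/paternal log-ratios against zero.

#' Allelic expression value
#'
#' `E = r / (n * l)`: reads covering one parental origin's alleles of a
#' gene, divided by the number of SNP positions in the gene and the
#' library size. Library size is expressed in millions of reads throughout
#' this package; any consistent unit cancels in maternal/paternal ratios.
#'
#' @param r Read count (>= 0).
#' @param n SNP positions in the gene (>= 1).
#' @param l Library size in millions of reads (> 0).
#' @return E value(s).
#' @examples
#' allele_expression(300, 3, 10)  # 10
#' @export
allele_expression <- function(r, n, l) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(l <= 0)) stop("l must be > 0", call. = FALSE)
  r / (n * l)
}

#' Origin-by-sex allelic expression summary per gene
#'
#' Computes E for every (gene, individual, origin) record and averages E
#' values of the same origin across all progeny of the same sex, yielding
#' four values per gene: E_maternal_in_females, E_paternal_in_females,
#' E_maternal_in_males, E_paternal_in_males. Sex-linked genes are assigned
#' a Y/X degeneration bin (> 0.75, 0.25-0.75, < 0.25) from the catalog's
#' control Yc/Xc ratio; autosomal genes are binned "autosomal". Genes with
#' no progeny observations are excluded and listed in the `"excluded"`
#' attribute.
#'
#' @param table Allelic count table (`gene_id`, `individual_id`, `sex`,
#'   `origin`, `reads`, `n_snps`, `library_size`).
#' @param catalog A `gene_catalog`.
#' @return Data frame with the four E columns and `yx_bin` per gene.
#' @export
summarize_origin <- function(table, catalog) {
  stopifnot(all(c("gene_id", "individual_id", "sex", "origin", "reads",
                  "n_snps", "library_size") %in% names(table)))
  table$E <- allele_expression(table$reads, table$n_snps, table$library_size)
  agg <- stats::aggregate(E ~ gene_id + sex + origin, data = table,
                          FUN = mean)
  agg$col <- paste0("E_", agg$origin, "_in_", agg$sex, "s")
  wide <- stats::reshape(agg[, c("gene_id", "col", "E")],
                         idvar = "gene_id", timevar = "col",
                         direction = "wide")
  names(wide) <- sub("^E\\.", "", names(wide))
  need <- c("E_maternal_in_females", "E_paternal_in_females",
            "E_maternal_in_males", "E_paternal_in_males")
  for (cc in setdiff(need, names(wide))) wide[[cc]] <- NA_real_
  wide <- wide[, c("gene_id", need)]
  gen <- catalog$genes[match(wide$gene_id, catalog$genes$gene_id), ,
                       drop = FALSE]
  yx <- gen$yx_ratio
  wide$yx_bin <- ifelse(gen$class == "autosomal", "autosomal",
                        ifelse(yx > 0.75, "Y/X>0.75",
                               ifelse(yx >= 0.25, "0.25-0.75", "Y/X<0.25")))
  excluded <- setdiff(catalog$genes$gene_id, wide$gene_id)
  rownames(wide) <- NULL
  attr(wide, "excluded") <- excluded
  wide
}

#' Test parent-of-origin expression bias
#'
#' For each Y/X bin (and the autosomal group), computes the distribution
#' of maternal/paternal E ratios in the requested sex and applies a
#' two-sided Wilcoxon signed-rank test of the log-ratios against 0. Genes
#' with a zero maternal or paternal E are excluded (undefined log-ratio)
#' and counted.
#'
#' @param summaries Output of [summarize_origin()].
#' @param sex `"female"` or `"male"`.
#' @param group Optional subset of `yx_bin` labels; default all present.
#' @return Data frame: `group`, `sex`, `n_genes`, `n_excluded`,
#'   `median_ratio`, `V`, `p`.
#' @export
imprinting_test <- function(summaries, sex = c("female", "male"),
                            group = NULL) {
  sex <- match.arg(sex)
  mcol <- paste0("E_maternal_in_", sex, "s")
  pcol <- paste0("E_paternal_in_", sex, "s")
  groups <- group %||% unique(summaries$yx_bin)
  missing_g <- setdiff(groups, summaries$yx_bin)
  if (length(missing_g)) {
    stop("empty group(s): ", paste(missing_g, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(groups, function(g) {
    sub <- summaries[summaries$yx_bin == g, , drop = FALSE]
    m <- sub[[mcol]]; p <- sub[[pcol]]
    ok <- !is.na(m) & !is.na(p) & m > 0 & p > 0
    lr <- log(m[ok] / p[ok])
    if (length(lr) < 2) {
      return(data.frame(group = g, sex = sex, n_genes = length(lr),
                        n_excluded = sum(!ok), median_ratio = NA_real_,
                        V = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    ties <- any(duplicated(abs(lr[lr != 0])))
    ht <- stats::wilcox.test(lr, mu = 0, exact = length(lr) <= 50 && !ties,
                             alternative = "two.sided")
    data.frame(group = g, sex = sex, n_genes = length(lr),
               n_excluded = sum(!ok),
               median_ratio = stats::median(exp(lr)),
               V = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
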