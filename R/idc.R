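# Classification of mutants as IDC-positive and localization of the
# compensation-factor region on the deletion map: the marker set deleted
# in every positive mutant and in no negative mutant.

#' Classify mutants as IDC-positive
#'
#' A mutant is positive when the median relative expression of every
#' available X-linked category (`X_del`, and `X_nondel` when present) is at
#' least `median_threshold` and the primary category's rank-sum p value
#' against the autosomal category is below `alpha` (default 0.01, the
#' significance convention of per-mutant category tables). Requiring both
#' X categories reflects that a compensation trigger acts on X-linked genes
#' generally, not only on those whose Y partner is deleted. Mutants with
#' no `X_del` genes are classified on `X_nondel` alone and flagged.
#'
#' @param summaries Category summary table from [summarize_categories()].
#' @param alpha Significance level (default 0.01).
#' @param median_threshold Minimum X median ratio (default 1.3).
#' @return Data frame: `mutant_id`, `x_del_median`, `x_nondel_median`,
#'   `p_used`, `idc_positive`, `based_on`.
#' @export
classify_idc <- function(summaries, alpha = 0.01, median_threshold = 1.3) {
  muts <- unique(summaries$mutant_id)
  rows <- lapply(muts, function(m) {
    sub <- summaries[summaries$mutant_id == m, , drop = FALSE]
    xd <- sub[sub$category == "X_del", , drop = FALSE]
    xn <- sub[sub$category == "X_nondel", , drop = FALSE]
    if (!nrow(xd) && !nrow(xn)) {
      stop("no X-linked category available for mutant ", m, call. = FALSE)
    }
    use <- if (nrow(xd) && xd$n_genes[1] > 0) xd else xn
    based_on <- use$category[1]
    medians <- c(if (nrow(xd) && xd$n_genes[1] > 0) xd$median_ratio[1],
                 if (nrow(xn) && xn$n_genes[1] > 0) xn$median_ratio[1])
    pos <- all(is.finite(medians)) && !is.na(use$p_vs_autosomal[1]) &&
      all(medians >= median_threshold) &&
      use$p_vs_autosomal[1] < alpha
    data.frame(
      mutant_id = m,
      x_del_median = if (nrow(xd)) xd$median_ratio[1] else NA_real_,
      x_nondel_median = if (nrow(xn)) xn$median_ratio[1] else NA_real_,
      p_used = use$p_vs_autosomal[1],
      idc_positive = pos,
      based_on = based_on,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Localize the compensation-factor region
#'
#' Returns the markers deleted in every positive mutant and deleted in no
#' negative mutant. Missing calls are permissive in positives (a missing
#' call does not veto membership) and conservative in negatives (treated as
#' non-deleted). Contiguity of the candidate set is verified on the
#' deletion-map order; a non-contiguous or empty result is reported whole
#' with a warning rather than truncated.
#'
#' @param matrix A `marker_matrix`.
#' @param map A `deletion_map` (or any ordered character vector of marker
#'   ids) giving the marker order.
#' @param positives,negatives Disjoint mutant id sets; positives must be
#'   non-empty.
#' @return List of class `factor_region`: `marker_ids` (in map order),
#'   `left_border`, `right_border`, `contiguous`, `n_markers`.
#' @export
localize_factor <- function(matrix, map, positives, negatives) {
  if (!length(positives)) stop("empty positive set", call. = FALSE)
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives must be disjoint", call. = FALSE)
  }
  calls <- matrix$calls
  missing_ids <- setdiff(c(positives, negatives), rownames(calls))
  if (length(missing_ids)) {
    stop("mutant(s) absent from matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  order_ids <- if (inherits(map, "deletion_map")) map$marker_order else map
  pos_calls <- calls[positives, , drop = FALSE]
  neg_calls <- calls[negatives, , drop = FALSE]
  # deleted (or missing) in every positive, with at least one observed 0
  in_all_pos <- apply(pos_calls, 2, function(v) {
    all(v %in% c(0L, NA)) && any(v == 0L, na.rm = TRUE)
  })
  in_no_neg <- if (nrow(neg_calls)) {
    apply(neg_calls, 2, function(v) !any(v == 0L, na.rm = TRUE))
  } else rep(TRUE, ncol(calls))
  candidate <- colnames(calls)[in_all_pos & in_no_neg]
  region <- order_ids[order_ids %in% candidate]
  contiguous <- TRUE
  if (length(region)) {
    idx <- match(region, order_ids)
    contiguous <- all(diff(sort(idx)) == 1L)
    if (!contiguous) {
      warning("candidate factor region is not contiguous on the map order")
    }
  } else {
    warning("empty factor region: positives share no exclusive deletion")
  }
  structure(list(
    marker_ids = region,
    left_border = if (length(region)) region[1L] else NA_character_,
    right_border = if (length(region)) region[length(region)] else NA_character_,
    contiguous = contiguous,
    n_markers = length(region)
  ), class = "factor_region")
}

#' @export
print.factor_region <- function(x, ...) {
  cat("factor_region:", x$n_markers, "markers",
      if (x$n_markers) paste0("(", x$left_border, " .. ", x$right_border, ")"),
      if (!x$contiguous) "[non-contiguous]", "\n")
  invisible(x)
}
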