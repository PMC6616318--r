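# Deleted-gene identification from expression and coverage evidence.
#
# Y-linked deletions: a Y gametolog is called deleted in a mutant when its
# expression signal is exactly zero there (hemizygous Y genes have no
# second copy to mask a deletion), provided the gene is testable: its X
# gametolog is expressed somewhere in the panel and both gametologs are
# expressed in non-irradiated controls. Autosomal hemizygosity: a
# heterozygous deletion halves copy number, so mutant/control RPKM ratios
# near 0.5 flag hemizygous genes; an optional contiguity filter keeps the
# largest run on the linkage map.

#' Reads per kilobase per million mapped reads
#'
#' @param mapped_reads Read count(s) for the gene.
#' @param length_bp Gene length in base pairs (> 0).
#' @param library_size Total mapped reads in the sample (> 0).
#' @return RPKM value(s): `reads / (length_bp/1000) / (library_size/1e6)`.
#' @examples
#' compute_rpkm(100, 2000, 5e6)  # 10
#' @export
compute_rpkm <- function(mapped_reads, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  mapped_reads / (length_bp / 1000) / (library_size / 1e6)
}

#' Call deleted Y-linked genes per mutant
#'
#' Applies three criteria per sex-linked gene and mutant:
#' (i) the Y gametolog has zero summed expression across the mutant's
#' replicates; (ii) the X gametolog exceeds `expression_floor` in at least
#' one mutant; (iii) both gametologs exceed the floor in controls
#' (replicate-averaged, mean over control individuals). Genes failing (ii)
#' or (iii) are reported `unclassifiable` rather than `not_deleted`.
#'
#' @param expression Long expression table (`gene_id`, `individual`,
#'   `replicate`, `fpkm`), as from [simulate_expression()].
#' @param catalog A `gene_catalog` (pairs X and Y gametologs).
#' @param mutants Character vector of mutant individual ids.
#' @param controls Character vector of control individual ids.
#' @param expression_floor FPKM above which a gene counts as expressed
#'   (default 0.5).
#' @return Data frame of class `deletion_calls`: `mutant_id`, `gene_id`
#'   (gametolog pair id), `call` in
#'   `{"deleted", "not_deleted", "unclassifiable"}`.
#' @export
call_y_deletions <- function(expression, catalog, mutants, controls,
                             expression_floor = 0.5) {
  missing_mut <- setdiff(mutants, unique(expression$individual))
  if (length(missing_mut)) {
    stop("mutant(s) absent from expression table: ",
         paste(missing_mut, collapse = ", "), call. = FALSE)
  }
  sl <- catalog$genes[catalog$genes$class == "sex_linked", , drop = FALSE]
  if (!nrow(sl)) {
    return(structure(data.frame(mutant_id = character(0),
                                gene_id = character(0),
                                call = character(0)),
                     class = c("deletion_calls", "data.frame")))
  }
  avg <- average_replicates(expression)
  val <- function(ids, inds) {
    sub <- avg[avg$gene_id %in% ids & avg$individual %in% inds, , drop = FALSE]
    # gene x individual mean FPKM matrix
    tapply(sub$fpkm, list(sub$gene_id, sub$individual), mean)
  }
  x_mut <- val(sl$x_id, mutants)
  ctrl_mean <- function(ids) {
    sub <- avg[avg$gene_id %in% ids & avg$individual %in% controls, ,
               drop = FALSE]
    tapply(sub$fpkm, sub$gene_id, mean)
  }
  x_ctrl <- ctrl_mean(sl$x_id)
  y_ctrl <- ctrl_mean(sl$y_id)
  # criterion (i) uses summed raw replicate signal, not the average
  ysum <- expression[expression$gene_id %in% sl$y_id &
                       expression$individual %in% mutants, , drop = FALSE]
  y_tot <- tapply(ysum$fpkm, list(ysum$gene_id, ysum$individual), sum)
  crit_ii <- apply(x_mut[sl$x_id, , drop = FALSE] > expression_floor, 1, any,
                   na.rm = TRUE)
  crit_iii <- (x_ctrl[sl$x_id] > expression_floor) &
    (y_ctrl[sl$y_id] > expression_floor)
  out <- expand.grid(mutant_id = mutants, gene_idx = seq_len(nrow(sl)),
                     stringsAsFactors = FALSE)
  out$gene_id <- sl$gene_id[out$gene_idx]
  yz <- y_tot[cbind(sl$y_id[out$gene_idx], out$mutant_id)] == 0
  testable <- crit_ii[out$gene_idx] & crit_iii[out$gene_idx]
  testable[is.na(testable)] <- FALSE
  out$call <- ifelse(!testable, "unclassifiable",
                     ifelse(yz, "deleted", "not_deleted"))
  out$gene_idx <- NULL
  rownames(out) <- NULL
  structure(out, class = c("deletion_calls", "data.frame"))
}

#' Extract the deleted-gene set of one mutant from a call table
#'
#' @param calls A `deletion_calls` data frame.
#' @param mutant_id Mutant identifier.
#' @return Character vector of gametolog pair ids called deleted.
#' @export
deleted_set <- function(calls, mutant_id) {
  calls$gene_id[calls$mutant_id == mutant_id & calls$call == "deleted"]
}

#' Call hemizygous autosomal genes from coverage
#'
#' Flags genes whose mutant/control RPKM ratio falls inside `window`
#' (default `[0.3, 0.7]`, symmetric around the hemizygous expectation of
#' 0.5) with control RPKM above `control_floor`. With `contiguity = TRUE`
#' and a catalog, only the largest run of flagged genes consecutive on one
#' linkage-group map is retained, tolerating up to `gap` unflagged genes
#' inside the run.
#'
#' @param mutant_cov,control_cov Coverage data frames (`gene_id`,
#'   `length_bp`, `mapped_reads`, `library_size`), one row per gene.
#' @param window Numeric ratio window, default `c(0.3, 0.7)`.
#' @param control_floor Minimum control RPKM for a gene to be testable.
#' @param contiguity Apply the linkage-map contiguity filter? When on, the
#'   whole span of the retained run is called hemizygous, including up to
#'   `gap` consecutive unflagged genes inside it: a heterozygous deletion
#'   is contiguous on the map, so interior coverage blips are rescued.
#' @param catalog Catalog supplying `linkage_group` and `map_pos` (required
#'   when `contiguity = TRUE`).
#' @param gap Number of consecutive unflagged genes tolerated inside a run
#'   (default 3, calibrated to the per-gene window miss rate of Poisson
#'   coverage at typical depth).
#' @return Data frame: `gene_id`, `rpkm_mutant`, `rpkm_control`, `ratio`,
#'   `hemizygous` (logical after any contiguity filtering).
#' @export
call_autosomal_hemizygous <- function(mutant_cov, control_cov,
                                      window = c(0.3, 0.7),
                                      control_floor = 1,
                                      contiguity = FALSE,
                                      catalog = NULL,
                                      gap = 3L) {
  shared <- intersect(mutant_cov$gene_id, control_cov$gene_id)
  if (!length(shared)) stop("no shared genes between samples", call. = FALSE)
  mc <- mutant_cov[match(shared, mutant_cov$gene_id), , drop = FALSE]
  cc <- control_cov[match(shared, control_cov$gene_id), , drop = FALSE]
  r_mut <- compute_rpkm(mc$mapped_reads, mc$length_bp, mc$library_size)
  r_ctl <- compute_rpkm(cc$mapped_reads, cc$length_bp, cc$library_size)
  ratio <- ifelse(r_ctl > 0, r_mut / r_ctl, NA_real_)
  flag <- !is.na(ratio) & ratio >= window[1] & ratio <= window[2] &
    r_ctl > control_floor
  out <- data.frame(gene_id = shared, rpkm_mutant = r_mut,
                    rpkm_control = r_ctl, ratio = ratio,
                    hemizygous = flag, stringsAsFactors = FALSE)
  if (contiguity) {
    if (is.null(catalog)) {
      stop("contiguity filtering needs a catalog with map positions",
           call. = FALSE)
    }
    gen <- catalog$genes[match(shared, catalog$genes$gene_id), , drop = FALSE]
    keep <- rep(FALSE, nrow(out))
    for (lg in unique(gen$linkage_group)) {
      idx <- which(gen$linkage_group == lg)
      idx <- idx[order(gen$map_pos[idx])]
      f <- out$hemizygous[idx]
      run <- best_run(f, gap)
      if (!is.null(run)) keep[idx[run]] <- TRUE
    }
    # retain only the overall largest run across linkage groups
    if (any(keep)) {
      by_lg <- tapply(keep, gen$linkage_group, sum)
      top <- names(by_lg)[which.max(by_lg)]
      keep[gen$linkage_group != top] <- FALSE
    }
    out$hemizygous <- keep
  }
  out
}

# largest run of TRUE values allowing up to `gap` interior FALSEs;
# returns the index range or NULL when nothing is flagged
best_run <- function(flag, gap) {
  pos <- which(flag)
  if (!length(pos)) return(NULL)
  best <- NULL
  best_n <- 0L
  start <- pos[1L]
  prev <- pos[1L]
  for (p in pos[-1L]) {
    if (p - prev - 1L > gap) {
      n <- sum(flag[start:prev])
      if (n > best_n) { best <- start:prev; best_n <- n }
      start <- p
    }
    prev <- p
  }
  n <- sum(flag[start:prev])
  if (n > best_n) best <- start:prev
  best
}

#' Genetic-map span of a flagged region
#'
#' @param gene_ids Genes in the flagged contiguous region.
#' @param catalog Catalog with `map_pos` in centimorgans.
#' @return Span in cM: `max(position) - min(position)`.
#' @export
region_span <- function(gene_ids, catalog) {
  pos <- catalog$genes$map_pos[match(gene_ids, catalog$genes$gene_id)]
  pos <- pos[!is.na(pos)]
  if (length(pos) < 2L) {
    stop("need at least two positioned genes to measure a span",
         call. = FALSE)
  }
  max(pos) - min(pos)
}
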