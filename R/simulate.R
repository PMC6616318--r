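# Synthetic data generation with planted ground truth.
#
# The generators emulate the structure of a Y-deletion mutant study in a
# dioecious plant: a panel of irradiation mutants genotyped at ordered STS
# markers, RNA-seq FPKM tables with technical replicates, genome coverage
# for a heterozygous autosomal deletion, allele-specific read counts from a
# genetic cross, and per-site bisulfite methylation calls. Every generator
# is deterministic given (seed, config) and returns or links to a truth
# record so downstream recovery tests are closed-loop.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with validation.
#' Defaults mirror the study design being emulated: a panel of ~100 mutants
#' genotyped at 160 markers, five of which delete the planted
#' compensation-factor interval; half of the X-linked genes respond to
#' factor deletion with a 2-fold upregulation (the dosage-restoring value);
#' technical-replicate noise with a coefficient of variation of 0.1; a
#' genetic cross with 20 male and 32 female progeny; CpG-dominant
#' methylation with ~2% CHG/CHH methylation.
#'
#' @param seed Integer seed; identical seed + config give bit-identical
#'   outputs from every generator.
#' @param n_autosomal_genes,n_sexlinked_genes Gene counts (>= 1 autosomal;
#'   sex-linked may be 0 for autosome-only analyses).
#' @param n_markers,n_mutants Marker and mutant panel dimensions.
#' @param factor_interval Integer pair: first and last marker (1-based, on
#'   the true order) of the planted compensation-factor region.
#' @param n_factor_mutants Number of mutants whose deletion covers the
#'   factor interval (these and only these are IDC-triggered).
#' @param compensated_fraction Fraction of X-linked genes that respond to
#'   factor deletion, in [0, 1].
#' @param compensation_fold Fold upregulation of responding X genes
#'   (default 2, the dosage-restoring value; 1.8 mimics the empirically
#'   observed peak).
#' @param replicate_cv Coefficient of variation of multiplicative
#'   technical-replicate noise.
#' @param n_replicates Technical replicates per individual (1 to 3).
#' @param n_controls Non-irradiated control individuals.
#' @param n_expression_mutants Number of mutants with expression data (the
#'   factor-deleting mutants are always included).
#' @param depth Mean per-gene read count for a diploid gene (coverage
#'   simulation) and mean site coverage (methylation simulation).
#' @param library_size Mapped reads per sample for RPKM denominators.
#' @param n_hemizygous Number of autosomal genes inside the planted
#'   heterozygous deletion carried by the dedicated autosomal mutant (the
#'   block is contiguous on one linkage-group map, so it is capped at the
#'   size of a linkage group).
#' @param n_linkage_groups Number of autosomal linkage groups genes are
#'   spread over (default 4).
#' @param missing_rate Probability a marker call is missing, at random.
#' @param max_deletion_markers Largest deletion run, in markers.
#' @param cross_progeny Named integer vector `c(male=, female=)`.
#' @param imprinting_bias Expected maternal/paternal expression ratio for
#'   X-linked genes in the cross (1 = no imprinting). Autosomal genes are
#'   always unbiased.
#' @param allelic_depth Mean total allelic reads per gene per progeny.
#' @param methylation_rates Named per-context methylation probabilities
#'   `c(CpG=, CHG=, CHH=)`.
#' @param methylation_shift Multiplier applied to mutant methylation rates
#'   of sex-linked genes (1 = mutant and control share rates).
#' @param sites_per_gene Cytosine sites simulated per gene per region.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_autosomal_genes = 500L,
                              n_sexlinked_genes = 400L,
                              n_markers = 160L,
                              n_mutants = 100L,
                              factor_interval = c(60L, 72L),
                              n_factor_mutants = 5L,
                              compensated_fraction = 0.5,
                              compensation_fold = 2,
                              replicate_cv = 0.1,
                              n_replicates = 3L,
                              n_controls = 3L,
                              n_expression_mutants = 17L,
                              depth = 50,
                              library_size = 5e6,
                              n_hemizygous = 49L,
                              n_linkage_groups = 4L,
                              missing_rate = 0,
                              max_deletion_markers = 40L,
                              cross_progeny = c(male = 20L, female = 32L),
                              imprinting_bias = 1,
                              allelic_depth = 50,
                              methylation_rates = c(CpG = 0.8, CHG = 0.02, CHH = 0.02),
                              methylation_shift = 1,
                              sites_per_gene = 20L) {
  cfg <- list(
    seed = as.integer(seed),
    n_autosomal_genes = as.integer(n_autosomal_genes),
    n_sexlinked_genes = as.integer(n_sexlinked_genes),
    n_markers = as.integer(n_markers),
    n_mutants = as.integer(n_mutants),
    factor_interval = as.integer(factor_interval),
    n_factor_mutants = as.integer(n_factor_mutants),
    compensated_fraction = compensated_fraction,
    compensation_fold = compensation_fold,
    replicate_cv = replicate_cv,
    n_replicates = as.integer(n_replicates),
    n_controls = as.integer(n_controls),
    n_expression_mutants = as.integer(n_expression_mutants),
    depth = depth,
    library_size = library_size,
    n_hemizygous = as.integer(n_hemizygous),
    n_linkage_groups = as.integer(n_linkage_groups),
    missing_rate = missing_rate,
    max_deletion_markers = as.integer(max_deletion_markers),
    cross_progeny = cross_progeny,
    imprinting_bias = imprinting_bias,
    allelic_depth = allelic_depth,
    methylation_rates = methylation_rates,
    methylation_shift = methylation_shift,
    sites_per_gene = as.integer(sites_per_gene)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_cfg(cfg$n_autosomal_genes >= 1, "n_autosomal_genes must be >= 1")
  stopifnot_cfg(cfg$n_sexlinked_genes >= 0, "n_sexlinked_genes must be >= 0")
  stopifnot_cfg(cfg$n_markers >= 2, "n_markers must be >= 2")
  stopifnot_cfg(cfg$n_mutants >= 1, "n_mutants must be >= 1")
  stopifnot_cfg(length(cfg$factor_interval) == 2 &&
                  all(cfg$factor_interval >= 1) &&
                  all(cfg$factor_interval <= cfg$n_markers) &&
                  cfg$factor_interval[1] <= cfg$factor_interval[2],
                "factor_interval endpoints must lie within [1, n_markers]")
  stopifnot_cfg(cfg$compensated_fraction >= 0 && cfg$compensated_fraction <= 1,
                "compensated_fraction must lie in [0, 1]")
  stopifnot_cfg(cfg$compensation_fold > 0, "compensation_fold must be > 0")
  stopifnot_cfg(cfg$replicate_cv >= 0, "replicate_cv must be >= 0")
  stopifnot_cfg(cfg$n_replicates >= 1 && cfg$n_replicates <= 3,
                "n_replicates must be in 1..3")
  stopifnot_cfg(cfg$n_factor_mutants >= 0 &&
                  cfg$n_factor_mutants <= cfg$n_mutants,
                "n_factor_mutants must be in 0..n_mutants")
  stopifnot_cfg(cfg$n_linkage_groups >= 1,
                "n_linkage_groups must be >= 1")
  stopifnot_cfg(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
                "missing_rate must be in [0, 1)")
  stopifnot_cfg(cfg$n_hemizygous >= 0 &&
                  cfg$n_hemizygous <= cfg$n_autosomal_genes,
                "n_hemizygous must be in 0..n_autosomal_genes")
  stopifnot_cfg(all(cfg$cross_progeny >= 1) &&
                  all(c("male", "female") %in% names(cfg$cross_progeny)),
                "cross_progeny must name male and female counts >= 1")
  stopifnot_cfg(cfg$imprinting_bias > 0, "imprinting_bias must be > 0")
  stopifnot_cfg(all(c("CpG", "CHG", "CHH") %in% names(cfg$methylation_rates)) &&
                  all(cfg$methylation_rates >= 0 & cfg$methylation_rates <= 1),
                "methylation_rates must name CpG, CHG, CHH probabilities")
  stopifnot_cfg(cfg$depth >= 0, "depth must be >= 0")
  stopifnot_cfg(cfg$library_size > 0, "library_size must be > 0")
  invisible(cfg)
}

#' Simulate a gene catalog
#'
#' Generates per-gene annotation: autosomal genes spread over four linkage
#' groups with centimorgan map positions, and sex-linked gametolog pairs
#' with synonymous divergence (dS) covering the three age strata
#' (dS < 0.04, 0.04-0.08, > 0.08), a baseline Yc/Xc expression ratio
#' covering the three Y-degeneration classes (< 0.3, 0.3-0.7, > 0.7), and
#' a marker assignment locating each Y gametolog on the marker backbone.
#' Bins are populated by construction: genes cycle through the three bins
#' before drawing a value inside the bin.
#'
#' @param config A [simulation_config()].
#' @return A list of class `gene_catalog` with elements `genes` (data frame)
#'   and `markers` (data frame with the true marker order).
#' @export
simulate_catalog <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "catalog"), {
    n_aut <- config$n_autosomal_genes
    n_sl <- config$n_sexlinked_genes
    aut <- data.frame(
      gene_id = sprintf("AUT%04d", seq_len(n_aut)),
      class = "autosomal",
      x_id = NA_character_,
      y_id = NA_character_,
      linkage_group = paste0("LG", rep_len(seq_len(config$n_linkage_groups),
                                           n_aut)),
      map_pos = NA_real_,
      length_bp = round(stats::runif(n_aut, 500, 5000)),
      dS = NA_real_,
      yx_ratio = NA_real_,
      marker_index = NA_integer_,
      stringsAsFactors = FALSE
    )
    # positions ordered within each linkage group
    for (lg in unique(aut$linkage_group)) {
      idx <- which(aut$linkage_group == lg)
      aut$map_pos[idx] <- sort(stats::runif(length(idx), 0, 100))
    }
    if (n_sl > 0) {
      ds_bin <- rep_len(1:3, n_sl)
      ds <- c(stats::runif(n_sl, 0.005, 0.039),
              stats::runif(n_sl, 0.041, 0.079),
              stats::runif(n_sl, 0.081, 0.20))
      ds <- ds[seq_len(n_sl) + (ds_bin - 1L) * n_sl]
      deg_bin <- rep_len(1:3, n_sl + 1L)[-1L]  # offset so bins cross dS bins
      yx <- c(stats::runif(n_sl, 0.05, 0.29),
              stats::runif(n_sl, 0.31, 0.69),
              stats::runif(n_sl, 0.71, 1.0))
      yx <- yx[seq_len(n_sl) + (deg_bin - 1L) * n_sl]
      sl <- data.frame(
        gene_id = sprintf("SL%04d", seq_len(n_sl)),
        class = "sex_linked",
        x_id = sprintf("SL%04dX", seq_len(n_sl)),
        y_id = sprintf("SL%04dY", seq_len(n_sl)),
        linkage_group = "XY",
        map_pos = NA_real_,
        length_bp = round(stats::runif(n_sl, 500, 5000)),
        dS = ds,
        yx_ratio = yx,
        marker_index = sample.int(config$n_markers, n_sl, replace = TRUE),
        stringsAsFactors = FALSE
      )
      genes <- rbind(aut, sl)
    } else {
      genes <- aut
    }
    markers <- data.frame(
      marker_id = sprintf("M%03d", seq_len(config$n_markers)),
      true_pos = seq_len(config$n_markers),
      stringsAsFactors = FALSE
    )
    structure(list(genes = genes, markers = markers, config = config),
              class = "gene_catalog")
  })
}

#' Simulate a Y-deletion mutant panel
#'
#' Each mutant carries zero, one, or two contiguous deletion runs on the
#' true marker order. A configured subset of mutants deletes a run covering
#' the planted factor interval; the runs of all other mutants avoid the
#' interval so that the IDC-triggered flag is exactly the planted set.
#' Marker columns of the returned matrix are shuffled relative to the true
#' order, so mapping has to recover the order. Missing calls are introduced
#' at random at `missing_rate`.
#'
#' @param catalog A `gene_catalog`.
#' @param config A [simulation_config()].
#' @return List with `matrix` (a `marker_matrix`) and `truth`
#'   (a `truth_record`).
#' @export
simulate_mutant_panel <- function(catalog, config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "panel"), {
    nm <- config$n_mutants
    nk <- config$n_markers
    fi <- config$factor_interval
    mutant_ids <- sprintf("MUT%03d", seq_len(nm))
    factor_mutants <- mutant_ids[seq_len(config$n_factor_mutants)]
    runs <- vector("list", nm)
    names(runs) <- mutant_ids
    draw_run_avoiding <- function() {
      # a contiguous run that misses the factor interval: runs overlapping
      # it are truncated at its boundary, so non-factor mutants can carry
      # deletions flanking the interval (which is what makes the interval's
      # borders identifiable by exclusion)
      len <- sample.int(min(config$max_deletion_markers, nk), 1L)
      start <- sample.int(nk - len + 1L, 1L)
      end <- start + len - 1L
      if (start >= fi[1] && end <= fi[2]) return(NULL)  # swallowed whole
      if (end >= fi[1] && start < fi[1]) end <- fi[1] - 1L
      if (start <= fi[2] && end > fi[2]) start <- fi[2] + 1L
      if (start > end || (start <= fi[2] && end >= fi[1])) return(NULL)
      c(start, end)
    }
    for (m in mutant_ids) {
      if (m %in% factor_mutants) {
        # run covering the whole factor interval, randomly extended
        ext_l <- sample.int(10L, 1L) - 1L
        ext_r <- sample.int(10L, 1L) - 1L
        r1 <- c(max(1L, fi[1] - ext_l), min(nk, fi[2] + ext_r))
        rs <- list(r1)
        if (stats::runif(1) < 0.3) {
          r2 <- draw_run_avoiding()
          if (!is.null(r2) && (r2[2] < r1[1] - 1L || r2[1] > r1[2] + 1L)) {
            rs <- c(rs, list(r2))
          }
        }
      } else {
        k <- sample(0:2, 1L, prob = c(0.15, 0.6, 0.25))
        rs <- list()
        while (length(rs) < k) {
          r <- draw_run_avoiding()
          if (is.null(r)) break
          overlaps <- any(vapply(rs, function(q) r[1] <= q[2] + 1L &&
                                   r[2] >= q[1] - 1L, logical(1)))
          if (!overlaps) rs <- c(rs, list(r))
        }
      }
      runs[[m]] <- rs
    }
    # presence/absence on the true order
    calls_true <- matrix(1L, nrow = nm, ncol = nk,
                         dimnames = list(mutant_ids, catalog$markers$marker_id))
    for (m in mutant_ids) {
      for (r in runs[[m]]) calls_true[m, r[1]:r[2]] <- 0L
    }
    deleted_markers <- lapply(mutant_ids, function(m) {
      catalog$markers$marker_id[calls_true[m, ] == 0L]
    })
    names(deleted_markers) <- mutant_ids
    sl <- catalog$genes[catalog$genes$class == "sex_linked", , drop = FALSE]
    deleted_y_genes <- lapply(mutant_ids, function(m) {
      del_idx <- which(calls_true[m, ] == 0L)
      sl$gene_id[sl$marker_index %in% del_idx]
    })
    names(deleted_y_genes) <- mutant_ids
    idc_triggered <- vapply(mutant_ids, function(m) {
      any(vapply(runs[[m]], function(r) r[1] <= fi[2] && r[2] >= fi[1],
                 logical(1)))
    }, logical(1))
    compensated <- if (nrow(sl)) {
      sl$gene_id[stats::runif(nrow(sl)) < config$compensated_fraction]
    } else character(0)
    hemi <- character(0)
    aut_mutant <- NA_character_
    if (config$n_hemizygous > 0) {
      # planted heterozygous block: contiguous on the LG1 map order
      lg1 <- catalog$genes[catalog$genes$linkage_group == "LG1", , drop = FALSE]
      lg1 <- lg1[order(lg1$map_pos), , drop = FALSE]
      nblock <- min(config$n_hemizygous, nrow(lg1))
      start <- if (nrow(lg1) > nblock) {
        sample.int(nrow(lg1) - nblock + 1L, 1L)
      } else 1L
      hemi <- lg1$gene_id[start:(start + nblock - 1L)]
      aut_mutant <- "MUTAUT"
    }
    # shuffle marker columns: the input order must not leak the true order
    shuffle <- sample.int(nk)
    calls <- calls_true[, shuffle, drop = FALSE]
    if (config$missing_rate > 0) {
      nas <- stats::runif(length(calls)) < config$missing_rate
      calls[nas] <- NA_integer_
      # keep the invariant that every marker has at least one call
      for (j in which(colSums(!is.na(calls)) == 0)) {
        calls[sample.int(nm, 1L), j] <- calls_true[sample.int(nm, 1L), shuffle[j]]
      }
    }
    truth <- structure(list(
      marker_order = catalog$markers$marker_id,
      deletion_runs = runs,
      deleted_markers = deleted_markers,
      deleted_y_genes = deleted_y_genes,
      idc_triggered = idc_triggered,
      compensated_genes = compensated,
      hemizygous_genes = hemi,
      aut_mutant = aut_mutant,
      factor_markers = catalog$markers$marker_id[fi[1]:fi[2]]
    ), class = "truth_record")
    mm <- marker_matrix(calls)
    list(matrix = mm, truth = truth)
  })
}

#' Construct a marker matrix
#'
#' @param calls Integer matrix, mutants in rows and markers in columns;
#'   1 = present, 0 = deleted, NA = missing. Dimnames are required.
#' @return Object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls) {
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must have mutant row names and marker column names",
         call. = FALSE)
  }
  if (!all(calls %in% c(0L, 1L, NA))) {
    stop("calls must be 0, 1 or NA", call. = FALSE)
  }
  all_missing <- colnames(calls)[colSums(!is.na(calls)) == 0]
  if (length(all_missing)) {
    stop("marker(s) with all calls missing: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  structure(list(calls = calls,
                 mutant_ids = rownames(calls),
                 marker_ids = colnames(calls)),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", length(x$mutant_ids), "mutants x",
      length(x$marker_ids), "markers;",
      sum(x$calls == 0L, na.rm = TRUE), "deleted calls,",
      sum(is.na(x$calls)), "missing\n")
  invisible(x)
}

# per-gene lognormal baseline FPKM, deterministic given the catalog seed
baseline_fpkm <- function(catalog) {
  cfg <- catalog$config
  with_seed(child_seed(cfg$seed, "catalog") + 7L, {
    genes <- catalog$genes
    base <- stats::rlnorm(nrow(genes), meanlog = log(20), sdlog = 1)
    names(base) <- genes$gene_id
    base
  })
}

#' Simulate an FPKM expression table
#'
#' Long-format FPKM per gene copy, individual and technical replicate.
#' Baselines are log-normal per gene; Y gametologs are expressed at the
#' gene's Yc/Xc ratio times the X baseline and drop to exactly zero when
#' deleted; X copies of compensated genes in IDC-triggered mutants are
#' multiplied by `compensation_fold` (fixed per gene across replicates);
#' hemizygous autosomal genes in the dedicated autosomal mutant sit at half
#' baseline (no dosage compensation); replicates carry multiplicative
#' log-normal noise with CV `replicate_cv`.
#'
#' @param catalog A `gene_catalog`.
#' @param truth A `truth_record` from [simulate_mutant_panel()].
#' @param config A [simulation_config()].
#' @return Data frame with columns `gene_id`, `individual`, `replicate`,
#'   `sample_id`, `tissue`, `fpkm`. Sex-linked gametologs appear as separate
#'   `gene_id` rows (`*X`, `*Y` suffixes).
#' @export
simulate_expression <- function(catalog, truth, config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "expression"), {
    genes <- catalog$genes
    base <- baseline_fpkm(catalog)
    controls <- sprintf("CTRL%d", seq_len(config$n_controls))
    all_mut <- names(truth$deletion_runs)
    factor_mut <- all_mut[truth$idc_triggered]
    n_expr <- min(config$n_expression_mutants, length(all_mut))
    others <- setdiff(all_mut, factor_mut)
    expr_mut <- c(factor_mut, others)[seq_len(n_expr)]
    individuals <- c(controls, expr_mut)
    if (!is.na(truth$aut_mutant)) individuals <- c(individuals, truth$aut_mutant)

    # expected expression per (copy, individual), before replicate noise
    rows <- list()
    comp <- genes$gene_id %in% truth$compensated_genes
    for (ind in individuals) {
      is_ctrl <- ind %in% controls
      x_expr <- base  # named by pair gene_id
      if (!is_ctrl && ind %in% names(truth$idc_triggered) &&
          isTRUE(truth$idc_triggered[[ind]])) {
        x_expr[comp & genes$class == "sex_linked"] <-
          x_expr[comp & genes$class == "sex_linked"] * config$compensation_fold
      }
      if (!is_ctrl && identical(ind, truth$aut_mutant)) {
        hz <- genes$gene_id %in% truth$hemizygous_genes
        x_expr[hz] <- x_expr[hz] * 0.5
      }
      sl <- genes$class == "sex_linked"
      y_expr <- base[sl] * genes$yx_ratio[sl]
      names(y_expr) <- genes$gene_id[sl]
      if (!is_ctrl && ind %in% names(truth$deleted_y_genes)) {
        y_expr[names(y_expr) %in% truth$deleted_y_genes[[ind]]] <- 0
      }
      ids <- c(ifelse(sl, genes$x_id, genes$gene_id), genes$y_id[sl])
      vals <- c(unname(x_expr), unname(y_expr))
      rows[[ind]] <- data.frame(gene_id = ids, individual = ind,
                                mean_fpkm = vals, stringsAsFactors = FALSE)
    }
    expected <- do.call(rbind, rows)
    nrep <- config$n_replicates
    cv <- config$replicate_cv
    sdlog <- sqrt(log(1 + cv^2))
    out <- expected[rep(seq_len(nrow(expected)), each = nrep), ]
    out$replicate <- rep(seq_len(nrep), times = nrow(expected))
    noise <- stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    out$fpkm <- out$mean_fpkm * noise
    out$fpkm[out$mean_fpkm == 0] <- 0  # deletions are exact zeros
    out$mean_fpkm <- NULL
    out$tissue <- "leaf"
    out$sample_id <- paste0(out$individual, "_r", out$replicate)
    rownames(out) <- NULL
    out[, c("gene_id", "individual", "replicate", "sample_id", "tissue", "fpkm")]
  })
}

#' Simulate genome coverage for the autosomal-deletion mutant and a control
#'
#' Per-gene mapped read counts are Poisson with mean `depth` times half the
#' copy number: diploid genes at `depth`, hemizygous genes at `depth/2`,
#' deleted Y gametologs at zero. Library sizes are recorded per sample.
#'
#' @inheritParams simulate_expression
#' @return Data frame with columns `gene_id`, `length_bp`, `sample_id`,
#'   `mapped_reads`, `library_size`; samples are `"mutant"` and `"control"`.
#' @export
simulate_coverage <- function(catalog, truth, config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "coverage"), {
    genes <- catalog$genes[catalog$genes$class == "autosomal", , drop = FALSE]
    cn_mut <- ifelse(genes$gene_id %in% truth$hemizygous_genes, 1, 2)
    lam_ctrl <- config$depth
    mk <- function(sample_id, cn) {
      data.frame(
        gene_id = genes$gene_id,
        length_bp = genes$length_bp,
        sample_id = sample_id,
        mapped_reads = stats::rpois(nrow(genes), lam_ctrl * cn / 2),
        library_size = config$library_size,
        stringsAsFactors = FALSE
      )
    }
    rbind(mk("control", 2), mk("mutant", cn_mut))
  })
}

#' Simulate allele-specific read counts for a genetic cross
#'
#' For each gene and progeny individual, total allelic reads are Poisson
#' and split between maternal and paternal origin binomially. Autosomal
#' genes split 1:1. X-linked genes in females split at
#' `imprinting_bias : 1` (maternal : paternal); in males the paternal
#' "allele" is the Y gametolog, expressed at the gene's Yc/Xc ratio, so the
#' maternal share is `bias : yx_ratio`. SNP count and library size (in
#' millions of reads) are recorded per gene and individual.
#'
#' @inheritParams simulate_expression
#' @return Data frame with columns `gene_id`, `individual_id`, `sex`,
#'   `origin`, `reads`, `n_snps`, `library_size`.
#' @export
simulate_allelic_counts <- function(catalog, config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "allelic"), {
    genes <- catalog$genes
    n_m <- config$cross_progeny[["male"]]
    n_f <- config$cross_progeny[["female"]]
    prog <- data.frame(
      individual_id = c(sprintf("P_M%02d", seq_len(n_m)),
                        sprintf("P_F%02d", seq_len(n_f))),
      sex = c(rep("male", n_m), rep("female", n_f)),
      library_size = round(stats::runif(n_m + n_f, 8, 12), 2),
      stringsAsFactors = FALSE
    )
    n_snps <- 1L + stats::rpois(nrow(genes), 2)
    names(n_snps) <- genes$gene_id
    b <- config$imprinting_bias
    grid <- expand.grid(g = seq_len(nrow(genes)), i = seq_len(nrow(prog)))
    total <- stats::rpois(nrow(grid), config$allelic_depth)
    sl <- genes$class[grid$g] == "sex_linked"
    male <- prog$sex[grid$i] == "male"
    p_mat <- rep(0.5, nrow(grid))
    p_mat[sl & !male] <- b / (b + 1)
    yx <- genes$yx_ratio[grid$g]
    p_mat[sl & male] <- b / (b + yx[sl & male])
    mat <- stats::rbinom(nrow(grid), total, p_mat)
    pat <- total - mat
    out <- data.frame(
      gene_id = rep(genes$gene_id[grid$g], 2L),
      individual_id = rep(prog$individual_id[grid$i], 2L),
      sex = rep(prog$sex[grid$i], 2L),
      origin = rep(c("maternal", "paternal"), each = nrow(grid)),
      reads = c(mat, pat),
      n_snps = rep(n_snps[grid$g], 2L),
      library_size = rep(prog$library_size[grid$i], 2L),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-site bisulfite methylation calls
#'
#' Sites are simulated for each gene in coding and 5' upstream regions,
#' with context labels CpG/CHG/CHH, Poisson coverage around `depth`, and
#' binomially methylated reads at the per-context rate. Mutant and control
#' share rates unless `methylation_shift` differs from 1, in which case
#' mutant rates of sex-linked genes are multiplied by the shift (capped at
#' 1).
#'
#' @inheritParams simulate_expression
#' @return Data frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `gene_id`, `region`, `sample_id`, `meth_count`, `unmeth_count`.
#' @export
simulate_methylation <- function(catalog, config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "methylation"), {
    genes <- catalog$genes
    ns <- config$sites_per_gene
    site_grid <- expand.grid(g = seq_len(nrow(genes)),
                             s = seq_len(ns),
                             region = c("coding", "upstream"),
                             stringsAsFactors = FALSE)
    n_sites <- nrow(site_grid)
    context <- sample(c("CpG", "CHG", "CHH"), n_sites, replace = TRUE,
                      prob = c(0.25, 0.30, 0.45))
    rate <- config$methylation_rates[context]
    sites <- data.frame(
      chrom = genes$linkage_group[site_grid$g],
      pos = site_grid$g * 10000L + site_grid$s +
        ifelse(site_grid$region == "upstream", 5000L, 0L),
      strand = sample(c("+", "-"), n_sites, replace = TRUE),
      context = context,
      gene_id = genes$gene_id[site_grid$g],
      region = site_grid$region,
      stringsAsFactors = FALSE
    )
    mk <- function(sample_id, r) {
      cov <- stats::rpois(n_sites, config$depth)
      meth <- stats::rbinom(n_sites, cov, pmin(r, 1))
      cbind(sites, data.frame(sample_id = sample_id, meth_count = meth,
                              unmeth_count = cov - meth,
                              stringsAsFactors = FALSE))
    }
    r_mut <- unname(rate)
    sl <- genes$class[site_grid$g] == "sex_linked"
    r_mut[sl] <- pmin(r_mut[sl] * config$methylation_shift, 1)
    out <- rbind(mk("control", unname(rate)), mk("mutant", r_mut))
    rownames(out) <- NULL
    out
  })
}

#' Write all synthetic inputs of one simulation to a directory
#'
#' Emits the catalog, marker matrix, expression, coverage, methylation and
#' allelic-count tables as TSV plus the truth record as JSON.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the generated objects.
#' @export
simulate_all <- function(config, dir = NULL) {
  catalog <- simulate_catalog(config)
  panel <- simulate_mutant_panel(catalog, config)
  expr <- simulate_expression(catalog, panel$truth, config)
  cov <- simulate_coverage(catalog, panel$truth, config)
  allelic <- simulate_allelic_counts(catalog, config)
  meth <- simulate_methylation(catalog, config)
  out <- list(catalog = catalog, matrix = panel$matrix, truth = panel$truth,
              expression = expr, coverage = cov, allelic = allelic,
              methylation = meth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tsv_file(catalog$genes, file.path(dir, "catalog.tsv"))
    mm <- panel$matrix
    mat_df <- data.frame(mutant_id = mm$mutant_ids, mm$calls,
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_file(mat_df, file.path(dir, "marker_matrix.tsv"))
    write_tsv_file(expr, file.path(dir, "expression.tsv"))
    write_tsv_file(cov, file.path(dir, "coverage.tsv"))
    write_tsv_file(allelic, file.path(dir, "allelic_counts.tsv"))
    write_tsv_file(meth, file.path(dir, "methylation.tsv"))
    jsonlite::write_json(
      list(marker_order = panel$truth$marker_order,
           deleted_markers = panel$truth$deleted_markers,
           deleted_y_genes = panel$truth$deleted_y_genes,
           idc_triggered = as.list(panel$truth$idc_triggered),
           compensated_genes = panel$truth$compensated_genes,
           hemizygous_genes = panel$truth$hemizygous_genes,
           factor_markers = panel$truth$factor_markers),
      file.path(dir, "truth.json"), auto_unbox = FALSE)
  }
  invisible(out)
}
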