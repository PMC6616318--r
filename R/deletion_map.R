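# Deletion-map construction: cluster markers sharing a deletion pattern
# into virtual markers, then order them so that the total number of
# presence/absence breakpoints across mutants is minimal. Under this
# objective each mutant's deletion tends to form contiguous runs
# (consecutive-ones relaxation), which is what makes an order "plausible"
# for a panel of contiguous deletions. The ends of the map are assumed to
# share the status of the adjacent marker, so only internal transitions
# count.

# normalized Hamming distance over positions where both calls are present
pattern_distance <- function(calls) {
  m <- ncol(calls)
  d <- matrix(0, m, m, dimnames = list(colnames(calls), colnames(calls)))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- calls[, i]; b <- calls[, j]
      ok <- !is.na(a) & !is.na(b)
      d[i, j] <- d[j, i] <- if (any(ok)) mean(a[ok] != b[ok]) else 0.5
    }
  }
  d
}

pattern_key <- function(v) paste(ifelse(is.na(v), "N", v), collapse = "")

#' Cluster markers into virtual markers
#'
#' Markers with identical call patterns are grouped; if more than `k`
#' distinct patterns exist, the closest patterns (Hamming distance over
#' comparable non-missing positions, normalised by their number) are merged
#' agglomeratively (average linkage) until `k` clusters remain. Each
#' cluster's consensus pattern is the per-mutant majority call with missing
#' values ignored (ties resolved to present).
#'
#' @param matrix A `marker_matrix`.
#' @param k Target number of virtual markers.
#' @return List of class `virtual_markers`; each element has `members`
#'   (marker ids) and `pattern` (consensus calls across mutants).
#' @export
cluster_markers <- function(matrix, k) {
  calls <- matrix$calls
  m <- ncol(calls)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > m) stop("k (", k, ") exceeds the number of markers (", m, ")",
                  call. = FALSE)
  keys <- apply(calls, 2, pattern_key)
  n_distinct <- length(unique(keys))
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct patterns (",
         n_distinct, ")", call. = FALSE)
  }
  if (k == n_distinct) {
    groups <- split(colnames(calls), keys)[unique(keys)]
  } else {
    d <- pattern_distance(calls)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, k = k)
    groups <- split(colnames(calls), cl)
  }
  vms <- lapply(unname(groups), function(members) {
    sub <- calls[, members, drop = FALSE]
    pattern <- apply(sub, 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) return(NA_integer_)
      if (mean(r == 0L) > 0.5) 0L else 1L
    })
    list(members = members, pattern = pattern)
  })
  structure(vms, class = "virtual_markers")
}

#' Count breakpoints of an ordered pattern sequence
#'
#' For each mutant, counts adjacent pairs of markers (in the given order)
#' whose non-missing calls differ. Missing calls are bridged: a missing run
#' between two equal calls contributes no breakpoint, between two different
#' calls exactly one. Map ends are assumed to continue the status of the
#' adjacent marker, so ends never contribute.
#'
#' @param patterns A matrix (mutants x ordered markers) or a list of
#'   per-marker call vectors in order.
#' @return Integer breakpoint count.
#' @export
breakpoint_count <- function(patterns) {
  if (is.list(patterns) && !is.matrix(patterns)) {
    patterns <- do.call(cbind, patterns)
  }
  if (is.null(dim(patterns)) || ncol(patterns) < 2L) {
    stop("need at least two ordered patterns", call. = FALSE)
  }
  total <- 0L
  for (i in seq_len(nrow(patterns))) {
    x <- patterns[i, ]
    x <- x[!is.na(x)]
    if (length(x) > 1L) total <- total + sum(diff(x) != 0)
  }
  as.integer(total)
}

# pairwise transition counts: d[i,j] = breakpoints contributed when marker j
# directly follows marker i (exact when patterns have no missing calls)
transition_matrix <- function(pat) {
  m <- ncol(pat)
  d <- matrix(0L, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- pat[, i]; b <- pat[, j]
      ok <- !is.na(a) & !is.na(b)
      d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
    }
  }
  d
}

# all permutations of 1..n as a matrix (rows = permutations)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

path_objective <- function(perm, d) {
  idx <- cbind(perm[-length(perm)], perm[-1L])
  sum(d[idx])
}

order_exhaustive <- function(pat, has_na) {
  m <- ncol(pat)
  perms <- all_perms(m)
  perms <- perms[perms[, 1L] < perms[, m], , drop = FALSE]  # reversal symmetry
  if (!has_na) {
    d <- transition_matrix(pat)
    obj <- rep(0L, nrow(perms))
    for (a in seq_len(m - 1L)) {
      obj <- obj + d[cbind(perms[, a], perms[, a + 1L])]
    }
  } else {
    obj <- apply(perms, 1, function(p) breakpoint_count(pat[, p, drop = FALSE]))
  }
  best <- min(obj)
  opt <- perms[obj == best, , drop = FALSE]
  list(orders = opt, objective = as.integer(best))
}

# greedy nearest-neighbour seeds from every start, refined by local search
# on the true breakpoint objective: 2-opt segment reversals plus or-opt
# relocation of short segments (length 1 and 2)
order_heuristic <- function(pat) {
  m <- ncol(pat)
  d <- transition_matrix(pat)
  evalo <- function(p) breakpoint_count(pat[, p, drop = FALSE])
  local_search <- function(perm, obj) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      # 2-opt: reverse a segment
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          cand <- perm
          cand[i:j] <- rev(cand[i:j])
          co <- evalo(cand)
          if (co < obj) {
            perm <- cand; obj <- co; improved <- TRUE
          }
        }
      }
      # or-opt: relocate a segment of length 1 or 2
      for (seg_len in 1:2) {
        if (m <= seg_len) next
        for (i in seq_len(m - seg_len + 1L)) {
          seg <- perm[i:(i + seg_len - 1L)]
          rest <- perm[-(i:(i + seg_len - 1L))]
          for (j in 0:length(rest)) {
            cand <- append(rest, seg, after = j)
            co <- evalo(cand)
            if (co < obj) {
              perm <- cand; obj <- co; improved <- TRUE
            }
          }
        }
      }
    }
    list(perm = perm, obj = obj)
  }
  best_perm <- NULL
  best_obj <- Inf
  for (start in seq_len(m)) {
    perm <- start
    left <- setdiff(seq_len(m), start)
    while (length(left)) {
      nxt <- left[which.min(d[perm[length(perm)], left])]
      perm <- c(perm, nxt)
      left <- setdiff(left, nxt)
    }
    res <- local_search(perm, evalo(perm))
    if (res$obj < best_obj) {
      best_obj <- res$obj
      best_perm <- res$perm
    }
  }
  list(orders = matrix(best_perm, 1), objective = as.integer(best_obj))
}

canonicalize_orders <- function(orders, ids) {
  # reversal-canonical: first id lexicographically smaller than last
  canon <- t(apply(orders, 1, function(p) {
    if (ids[p[1L]] > ids[p[length(p)]]) rev(p) else p
  }))
  canon <- unique(canon)
  key <- apply(canon, 1, paste, collapse = ",")
  canon[order(key), , drop = FALSE]
}

#' Order virtual markers by breakpoint minimisation
#'
#' Finds an order of the virtual markers minimising [breakpoint_count()]
#' over their consensus patterns. `method = "exhaustive"` enumerates all
#' orders up to whole-map reversal (allowed up to `cap` virtual markers)
#' and reports every co-optimal order; `method = "heuristic"` uses greedy
#' nearest-neighbour seeding from every start plus 2-opt segment-reversal
#' refinement.
#'
#' @param virtuals A `virtual_markers` list from [cluster_markers()].
#' @param method `"exhaustive"` or `"heuristic"`.
#' @param cap Largest instance solved exhaustively (default 10).
#' @return Object of class `deletion_map` with the ordered virtual markers,
#'   the flattened marker order, the objective value, and the co-optimal
#'   order count (exhaustive mode).
#' @export
order_markers <- function(virtuals, method = c("heuristic", "exhaustive"),
                          cap = 10L) {
  method <- match.arg(method)
  m <- length(virtuals)
  if (m < 2L) stop("need at least two virtual markers", call. = FALSE)
  pat <- do.call(cbind, lapply(virtuals, `[[`, "pattern"))
  has_na <- anyNA(pat)
  if (method == "exhaustive") {
    if (m > cap) {
      stop("exhaustive ordering limited to ", cap,
           " virtual markers; use method = \"heuristic\"", call. = FALSE)
    }
    res <- order_exhaustive(pat, has_na)
  } else {
    res <- order_heuristic(pat)
  }
  ids <- vapply(virtuals, function(v) v$members[1L], character(1))
  orders <- canonicalize_orders(res$orders, ids)
  best <- orders[1L, ]
  ordered_vm <- virtuals[best]
  marker_order <- unlist(lapply(ordered_vm, `[[`, "members"))
  structure(list(
    order = best,
    ordered_virtual_markers = ordered_vm,
    marker_order = marker_order,
    within_cluster_orders = lapply(ordered_vm, `[[`, "members"),
    uninformative = stats::setNames(rep(FALSE, length(marker_order)),
                                    marker_order),
    total_breakpoints = res$objective,
    alternative_optima = nrow(orders),
    co_optimal_orders = orders,
    method = method
  ), class = "deletion_map")
}

#' @export
print.deletion_map <- function(x, ...) {
  cat("deletion_map:", length(x$ordered_virtual_markers), "virtual markers,",
      length(x$marker_order), "markers; total breakpoints",
      x$total_breakpoints, "\n")
  if (!is.na(x$alternative_optima)) {
    cat("co-optimal orders (up to reversal):", x$alternative_optima, "\n")
  }
  cat("order:", paste(utils::head(x$marker_order, 10), collapse = " "),
      if (length(x$marker_order) > 10) "...\n" else "\n")
  invisible(x)
}

#' Refine marker order within each virtual marker
#'
#' Recursively orders the member markers of every cluster by the same
#' breakpoint objective, restricted to the cluster's raw calls with the
#' consensus patterns of the flanking clusters as fixed boundary context
#' (map ends have no context, matching the end-status assumption). Clusters
#' whose members share an identical pattern are left in input order and
#' flagged uninformative.
#'
#' @param map A `deletion_map`.
#' @param matrix The `marker_matrix` the map was built from.
#' @param cap Largest within-cluster instance ordered exhaustively.
#' @return The map with `marker_order`, `within_cluster_orders` and
#'   `uninformative` updated; `total_breakpoints` is re-evaluated on the
#'   full marker-level order.
#' @export
order_within_clusters <- function(map, matrix, cap = 8L) {
  vms <- map$ordered_virtual_markers
  if (!length(vms)) return(map)
  calls <- matrix$calls
  nvm <- length(vms)
  within <- vector("list", nvm)
  uninf <- map$uninformative
  for (ci in seq_len(nvm)) {
    members <- vms[[ci]]$members
    if (length(members) <= 1L) {
      within[[ci]] <- members
      next
    }
    keys <- apply(calls[, members, drop = FALSE], 2, pattern_key)
    if (length(unique(keys)) == 1L) {
      within[[ci]] <- members
      uninf[members] <- TRUE
      next
    }
    # duplicate patterns inside a mixed cluster are individually uninformative
    uninf[members[duplicated(keys)]] <- TRUE
    left <- if (ci > 1L) vms[[ci - 1L]]$pattern else NULL
    right <- if (ci < nvm) vms[[ci + 1L]]$pattern else NULL
    sub <- calls[, members, drop = FALSE]
    ctx <- cbind(left, sub, right)
    fixed_l <- as.integer(!is.null(left))
    n_mem <- length(members)
    evalo <- function(p) {
      cols <- c(if (fixed_l) 1L, p + fixed_l,
                if (!is.null(right)) n_mem + fixed_l + 1L)
      breakpoint_count(ctx[, cols, drop = FALSE])
    }
    if (n_mem <= cap) {
      perms <- all_perms(n_mem)
      obj <- apply(perms, 1, evalo)
      best <- perms[which.min(obj), ]
    } else {
      # greedy insertion then pairwise-swap refinement
      best <- seq_len(n_mem)
      obj <- evalo(best)
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (i in seq_len(n_mem - 1L)) {
          for (j in (i + 1L):n_mem) {
            cand <- best
            cand[c(i, j)] <- cand[c(j, i)]
            if (evalo(cand) < obj) {
              best <- cand; obj <- evalo(best); improved <- TRUE
            }
          }
        }
      }
    }
    within[[ci]] <- members[best]
  }
  map$within_cluster_orders <- within
  map$marker_order <- unlist(within)
  map$uninformative <- uninf[map$marker_order]
  map$total_breakpoints <- breakpoint_count(
    calls[, map$marker_order, drop = FALSE])
  map
}

#' Build a deletion map from a marker matrix
#'
#' Convenience wrapper: cluster into `k` virtual markers, order them, and
#' refine the order within clusters.
#'
#' @param matrix A `marker_matrix`.
#' @param k Number of virtual markers (default 14).
#' @param method Ordering method passed to [order_markers()].
#' @param cap Exhaustive-search cap.
#' @return A `deletion_map`.
#' @export
build_deletion_map <- function(matrix, k = 14L,
                               method = c("heuristic", "exhaustive"),
                               cap = 10L) {
  method <- match.arg(method)
  vms <- cluster_markers(matrix, k)
  map <- order_markers(vms, method = method, cap = cap)
  order_within_clusters(map, matrix)
}

#' Export a deletion map as a data frame
#'
#' One row per marker in map order, with its virtual-marker index and the
#' uninformative flag.
#'
#' @param map A `deletion_map`.
#' @return Data frame with columns `rank`, `marker_id`, `virtual_marker`,
#'   `uninformative`.
#' @export
map_as_table <- function(map) {
  vm_idx <- rep(seq_along(map$within_cluster_orders),
                lengths(map$within_cluster_orders))
  data.frame(
    rank = seq_along(map$marker_order),
    marker_id = map$marker_order,
    virtual_marker = vm_idx,
    uninformative = unname(map$uninformative),
    stringsAsFactors = FALSE
  )
}
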