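#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# All generators route through this so that identical (seed, config) pairs
# give bit-identical output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage child seeds fanned out from one global seed.
# Keeps every stage's stream independent while staying inside 32-bit range.
child_seed <- function(seed, stage) {
  offsets <- c(
    catalog = 101L, panel = 211L, expression = 307L, coverage = 401L,
    allelic = 503L, methylation = 601L, analysis = 701L, pipeline = 809L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as a tab-separated file
#'
#' Plain TSV writer used for all pipeline outputs (no quoting, no row names).
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by this package
#'
#' @param path File path.
#' @param required_cols Optional character vector of column names that must
#'   be present; a missing column is an error naming the file.
#' @return A data frame.
#' @export
read_tsv_file <- function(path, required_cols = NULL) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(x))
    if (length(missing)) {
      stop("file ", path, " lacks required columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  x
}
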