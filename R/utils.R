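#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are pure
#' functions of their arguments and never disturb the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# single positive integer-ish scalar check
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a table of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)` throughout the package,
#' matching BED conventions.
#'
#' @param x A data.frame with columns `chrom`, `start`, `end` (and optionally
#'   `strand`).
#' @param name Label used in error messages.
#' @return `x`, with `chrom` coerced to character, invisibly usable.
#' @keywords internal
check_intervals <- function(x, name = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop(sprintf("'%s' must be a data.frame with chrom/start/end", name),
         call. = FALSE)
  }
  x$chrom <- as.character(x$chrom)
  if (nrow(x) && any(x$start < 0 | x$end <= x$start)) {
    stop(sprintf("'%s' has invalid intervals (need 0 <= start < end)", name),
         call. = FALSE)
  }
  x
}

# order intervals by chromosome then start then end
sort_intervals <- function(x) {
  if (!nrow(x)) return(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

# convert one chromosome's intervals to an IRanges (closed integer ranges on
# 0-based half-open input: [start, end) -> IRanges(start + 1, end))
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}
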