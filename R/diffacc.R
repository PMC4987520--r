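#' Construct a region count matrix
#'
#' The container for per-region fragment counts across libraries, with
#' library-size normalization: each library's counts are scaled by
#' `mean(library_totals) / library_total`, so normalized totals are equal
#' across libraries.
#'
#' @param regions Interval data.frame (`chrom`, `start`, `end`), disjoint.
#' @param counts Integer matrix, regions x libraries.
#' @param condition Character vector, condition label per library.
#' @param library_totals Total fragment count per library (defaults to
#'   column sums of `counts`).
#' @return Object of class `region_counts`: list with `regions`, `counts`,
#'   `library_totals`, `normalized`, `condition`.
#' @export
new_region_counts <- function(regions, counts, condition,
                              library_totals = NULL) {
  regions <- check_intervals(regions, "regions")
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(regions)) {
    stop("'counts' must have one row per region", call. = FALSE)
  }
  if (any(counts < 0)) stop("'counts' must be >= 0", call. = FALSE)
  condition <- as.character(rep_len(condition, ncol(counts)))
  if (is.null(library_totals)) library_totals <- colSums(counts)
  if (any(library_totals < 0)) {
    stop("library totals must be non-negative", call. = FALSE)
  }
  # empty libraries (all-zero counts) scale by 1 rather than divide by 0
  scale <- ifelse(library_totals > 0,
                  mean(library_totals) / library_totals, 1)
  normalized <- sweep(counts, 2L, scale, "*")
  structure(list(regions = regions, counts = counts,
                 library_totals = library_totals, normalized = normalized,
                 condition = condition),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("region_counts: %d regions x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$condition, collapse = ", ")))
  invisible(x)
}

#' Merge two peak sets into a common region universe
#'
#' The union of both sets with overlapping or bookended regions merged into
#' maximal intervals; the shared coordinate system that per-region
#' comparison between conditions requires.
#'
#' @param peaks_a,peaks_b Interval data.frames.
#' @return Sorted, disjoint interval data.frame.
#' @examples
#' build_universe(data.frame(chrom = "chr1", start = 100, end = 200),
#'                data.frame(chrom = "chr1", start = 150, end = 300))
#' @export
build_universe <- function(peaks_a, peaks_b) {
  a <- check_intervals(peaks_a, "peaks_a")
  b <- check_intervals(peaks_b, "peaks_b")
  all <- rbind(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")])
  if (!nrow(all)) return(all)
  out <- lapply(sort(unique(all$chrom)), function(cn) {
    x <- all[all$chrom == cn, , drop = FALSE]
    r <- IRanges::reduce(as_iranges0(x$start, x$end))
    data.frame(chrom = cn, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count fragments per region per library
#'
#' Each fragment increments the count of every region it overlaps by at
#' least 1 bp (a fragment spanning two regions counts in both). Regions must
#' be disjoint; merge them first with [build_universe()].
#'
#' @param regions Disjoint interval data.frame.
#' @param fragment_list Named list of fragment data.frames, one per library.
#' @param condition Condition label per library (defaults to library
#'   names).
#' @return A `region_counts` object; `library_totals` are the full fragment
#'   counts of each library (including fragments outside all regions).
#' @export
count_fragments <- function(regions, fragment_list, condition = NULL) {
  regions <- sort_intervals(check_intervals(regions, "regions"))
  rownames(regions) <- NULL
  if (nrow(regions) > 1L) {
    ov <- unlist(lapply(split(seq_len(nrow(regions)), regions$chrom),
                        function(i) {
                          if (length(i) < 2L) return(FALSE)
                          regions$start[i][-1] < regions$end[i][-length(i)]
                        }))
    if (any(ov)) {
      stop("regions overlap; build a merged universe first", call. = FALSE)
    }
  }
  if (!is.list(fragment_list) || !length(fragment_list)) {
    stop("'fragment_list' must be a non-empty list of fragment tables",
         call. = FALSE)
  }
  if (is.null(names(fragment_list))) {
    names(fragment_list) <- paste0("lib", seq_along(fragment_list))
  }
  counts <- vapply(fragment_list, function(f) {
    f <- check_intervals(f, "fragments")
    n <- integer(nrow(regions))
    for (cn in unique(regions$chrom)) {
      i <- which(regions$chrom == cn)
      fc <- f[f$chrom == cn, , drop = FALSE]
      if (!nrow(fc)) next
      n[i] <- IRanges::countOverlaps(
        as_iranges0(regions$start[i], regions$end[i]),
        as_iranges0(fc$start, fc$end))
    }
    n
  }, integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(NULL, names(fragment_list)))
  totals <- vapply(fragment_list, nrow, integer(1))
  if (is.null(condition)) condition <- names(fragment_list)
  new_region_counts(regions, counts, condition, library_totals = totals)
}

#' Call differentially accessible regions
#'
#' The decision rule: a region is differentially accessible when one
#' condition has at least `min_ratio` times more (normalized) reads than the
#' other AND the Poisson upper-tail probability of the larger count given
#' the smaller as expectation is at most `max_p`; both thresholds are
#' inclusive. Replicate libraries are summed within condition after
#' library-size normalization, and condition totals are rescaled to a
#' common replicate number so unequal designs do not bias the ratio. The
#' pseudocount is added to both terms of the ratio and to the Poisson
#' expectation, stabilizing calls at low counts.
#'
#' @param rc A `region_counts` object with exactly two condition labels.
#' @param min_ratio Minimum fold difference (default 4, inclusive).
#' @param max_p Maximum P-value (default 0.01, inclusive).
#' @param pseudocount Added to normalized condition totals (default 1).
#' @return Object of class `diff_calls`: a data.frame with the region
#'   coordinates, normalized condition totals `x_a` and `x_b`, `ratio`
#'   (larger/smaller), `pval`, `direction` (`A`/`B`/`none` in the order of
#'   the sorted condition labels) and `differential`. Parameters are kept in
#'   attributes.
#' @examples
#' rc <- simulate_atac_counts(50, 5, fold = 8, base_mean = 200, seed = 1)
#' dc <- classify_differential(rc)
#' summary(dc)
#' @export
classify_differential <- function(rc, min_ratio = 4, max_p = 0.01,
                                  pseudocount = 1) {
  stopifnot(inherits(rc, "region_counts"))
  conds <- sort(unique(rc$condition))
  if (length(conds) != 2L) {
    stop("exactly two conditions required, got ",
         length(conds), call. = FALSE)
  }
  if (pseudocount < 0) stop("'pseudocount' must be >= 0", call. = FALSE)
  cols_a <- rc$condition == conds[1L]
  cols_b <- rc$condition == conds[2L]
  n_bar <- mean(c(sum(cols_a), sum(cols_b)))
  x_a <- rowSums(rc$normalized[, cols_a, drop = FALSE]) *
    (n_bar / sum(cols_a))
  x_b <- rowSums(rc$normalized[, cols_b, drop = FALSE]) *
    (n_bar / sum(cols_b))
  hi <- pmax(x_a, x_b)
  lo <- pmin(x_a, x_b)
  ratio <- (hi + pseudocount) / (lo + pseudocount)
  pval <- poisson_upper_tail(round(hi), lo + pseudocount)
  differential <- ratio >= min_ratio & pval <= max_p
  direction <- ifelse(!differential, "none",
                      ifelse(x_a >= x_b, conds[1L], conds[2L]))
  out <- cbind(rc$regions,
               data.frame(x_a = x_a, x_b = x_b, ratio = ratio, pval = pval,
                          direction = direction,
                          differential = differential,
                          stringsAsFactors = FALSE))
  names(out)[names(out) == "x_a"] <- paste0("x_", conds[1L])
  names(out)[names(out) == "x_b"] <- paste0("x_", conds[2L])
  attr(out, "params") <- list(min_ratio = min_ratio, max_p = max_p,
                              pseudocount = pseudocount,
                              conditions = conds)
  class(out) <- c("diff_calls", "data.frame")
  out
}

#' @export
print.diff_calls <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "diff_calls: %d / %d regions differential (ratio >= %g, P <= %g, pseudocount %g)\n",
    sum(x$differential), nrow(x), p$min_ratio, p$max_p, p$pseudocount))
  print.data.frame(utils::head(x[x$differential, , drop = FALSE], 10L))
  invisible(x)
}

#' @export
summary.diff_calls <- function(object, ...) {
  p <- attr(object, "params")
  tab <- table(factor(object$direction,
                      levels = c(p$conditions, "none")))
  cat(sprintf("Differential accessibility (ratio >= %g, P <= %g):\n",
              p$min_ratio, p$max_p))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(tab)
}
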