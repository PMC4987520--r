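#' Remove clonal duplicate reads
#'
#' Reads mapping to the same position are counted only once to reduce clonal
#' PCR-amplification effects. The duplicate key is (chrom, 5' position,
#' strand) by default, the standard strand-aware definition; set
#' `by_strand = FALSE` to collapse across strands.
#'
#' @param reads Aligned-read data.frame (`chrom`, `pos`, `strand`, `length`).
#' @param by_strand Include strand in the duplicate key (default `TRUE`).
#' @return The reads with duplicates removed, first occurrence kept, input
#'   order preserved.
#' @examples
#' r <- data.frame(chrom = "chr1", pos = c(100, 100, 100),
#'                 strand = c("+", "+", "-"), length = 50)
#' nrow(dedupe_reads(r))  # 2
#' @export
dedupe_reads <- function(reads, by_strand = TRUE) {
  if (!nrow(reads)) return(reads)
  key <- if (by_strand) paste(reads$chrom, reads$pos, reads$strand)
         else paste(reads$chrom, reads$pos)
  out <- reads[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend reads into fixed-length fragments
#'
#' Each read is replaced by an `ext`-bp fragment running in its 3'
#' direction, approximating the sequenced fragment from its 5' end: a `+`
#' strand read at `pos` becomes `[pos, pos + ext)`; a `-` strand read
#' becomes `[pos + length - ext, pos + length)` (its 5' end is the rightmost
#' base). Fragments are clipped to `[0, chromosome length)`. With
#' `mode = "append"` the extension is instead added beyond the read's 3'
#' end, giving fragments of `length + ext` bp.
#'
#' @param reads Aligned-read data.frame.
#' @param chrom_sizes Named vector of chromosome lengths for clipping.
#' @param ext Extension length in bp (default 150).
#' @param mode `"fragment"` (default; read replaced by an `ext`-bp fragment)
#'   or `"append"` (read kept and extended by `ext` further bp).
#' @return data.frame of fragments (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @examples
#' cs <- c(chr1 = 1000)
#' extend_reads(data.frame(chrom = "chr1", pos = 100, strand = "+",
#'                         length = 50), cs)        # [100, 250)
#' extend_reads(data.frame(chrom = "chr1", pos = 400, strand = "-",
#'                         length = 50), cs)        # [300, 450)
#' @export
extend_reads <- function(reads, chrom_sizes, ext = 150L,
                         mode = c("fragment", "append")) {
  mode <- match.arg(mode)
  check_count(ext, "ext", min = 1L)
  if (!nrow(reads)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  if (!all(reads$strand %in% c("+", "-"))) {
    stop("unknown strand value; expected '+' or '-'", call. = FALSE)
  }
  unknown <- !(reads$chrom %in% names(chrom_sizes))
  if (any(unknown)) {
    stop("read(s) on chromosome absent from chrom_sizes: ",
         paste(unique(reads$chrom[unknown]), collapse = ", "),
         call. = FALSE)
  }
  plus <- reads$strand == "+"
  if (mode == "fragment") {
    start <- ifelse(plus, reads$pos, reads$pos + reads$length - ext)
    end <- ifelse(plus, reads$pos + ext, reads$pos + reads$length)
  } else {
    start <- ifelse(plus, reads$pos, reads$pos - ext)
    end <- ifelse(plus, reads$pos + reads$length + ext,
                  reads$pos + reads$length)
  }
  lim <- unname(chrom_sizes[reads$chrom])
  data.frame(chrom = reads$chrom,
             start = as.integer(pmax(start, 0L)),
             end = as.integer(pmin(end, lim)),
             stringsAsFactors = FALSE)
}

#' Count fragments overlapping fixed-width genome windows
#'
#' The genome is tiled with `window`-bp windows (the last window of a
#' chromosome may be shorter) and every fragment increments the count of
#' every window it overlaps by at least 1 bp.
#'
#' @param fragments Fragment data.frame (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of chromosome lengths (a `toy_genome` is
#'   also accepted).
#' @param window Window width in bp (default 50).
#' @return Named list, one integer vector of per-window counts per
#'   chromosome.
#' @examples
#' count_windows(data.frame(chrom = "chr1", start = 100, end = 250),
#'               c(chr1 = 500))$chr1   # windows 2,3,4 hit
#' @export
count_windows <- function(fragments, chrom_sizes, window = 50L) {
  if (inherits(chrom_sizes, "toy_genome")) chrom_sizes <- chrom_sizes$chrom_sizes
  check_count(window, "window", min = 1L)
  fragments <- check_intervals(fragments, "fragments")
  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("fragment(s) on unknown chromosome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- lapply(names(chrom_sizes), function(cn) {
    n_win <- as.integer(ceiling(chrom_sizes[[cn]] / window))
    counts <- integer(n_win)
    f <- fragments[fragments$chrom == cn, , drop = FALSE]
    if (nrow(f)) {
      first <- pmax(f$start %/% window, 0L) + 1L
      last <- pmin((f$end - 1L) %/% window, n_win - 1L) + 1L
      keep <- first <= n_win & last >= 1L
      first <- pmax(first[keep], 1L); last <- last[keep]
      # difference-array trick: +1 at first window, -1 after last, cumsum
      delta <- integer(n_win + 1L)
      tf <- tabulate(first, nbins = n_win + 1L)
      tl <- tabulate(last + 1L, nbins = n_win + 1L)
      counts <- cumsum(tf - tl)[seq_len(n_win)]
    }
    counts
  })
  names(out) <- names(chrom_sizes)
  out
}

#' Expected IP window count from the input library
#'
#' Scales the input window count by the ratio of library totals so IP and
#' input are comparable, then applies a floor: windows with little or no
#' input coverage receive at least `lam_floor` expected fragments. Without a
#' floor, a window with zero input would make any stray IP read look
#' infinitely significant.
#'
#' @param input_count Input fragment count(s) per window.
#' @param ip_total,input_total Total read counts of the IP and input
#'   libraries (after duplicate removal); both must be positive.
#' @param lam_floor Minimum expected count (default 0; `call_peaks()` uses
#'   the genome-wide mean normalized input per window).
#' @return Expected count lambda per window.
#' @examples
#' normalize_input(4, ip_total = 1000, input_total = 500)  # 8
#' @export
normalize_input <- function(input_count, ip_total, input_total,
                            lam_floor = 0) {
  if (ip_total <= 0 || input_total <= 0) {
    stop("library totals must be positive", call. = FALSE)
  }
  if (any(input_count < 0)) stop("'input_count' must be >= 0", call. = FALSE)
  pmax(input_count * (ip_total / input_total), lam_floor)
}

#' Poisson upper-tail probability P(X >= k)
#'
#' The window enrichment test: the probability of observing at least the IP
#' count `k` under a Poisson null with expectation `lam` taken from the
#' normalized input. Returns 1 when `k = 0` and 0 when `lam = 0` with
#' `k > 0`.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lam Expected count(s) under the null, >= 0.
#' @return P(X >= k) for X ~ Poisson(lam), vectorized.
#' @examples
#' poisson_upper_tail(5, 1)    # ~3.66e-3
#' poisson_upper_tail(0, 5)    # 1
#' @export
poisson_upper_tail <- function(k, lam) {
  if (any(k < 0)) stop("'k' must be >= 0", call. = FALSE)
  if (any(lam < 0)) stop("'lam' must be >= 0", call. = FALSE)
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' Flag significant and qualifying windows
#'
#' A window is significant when its P-value is strictly below `alpha`
#' (default 1e-3). A window qualifies as peak evidence only when it and both
#' of its immediate neighbours on the same chromosome are significant;
#' terminal windows, lacking a neighbour, can be significant but never
#' qualify.
#'
#' @param stats Window-stats data.frame with columns `chrom` and `pval`,
#'   rows in genomic order within each chromosome.
#' @param alpha Significance threshold (strict `<`; default 1e-3).
#' @return `stats` with logical columns `significant` and `qualifying`
#'   added/overwritten.
#' @examples
#' s <- data.frame(chrom = "chr1", pval = c(0.5, 1e-4, 1e-4, 1e-4, 0.5))
#' flag_windows(s)$qualifying   # F F T F F
#' @export
flag_windows <- function(stats, alpha = 1e-3) {
  stopifnot(is.data.frame(stats), all(c("chrom", "pval") %in% names(stats)))
  sig <- stats$pval < alpha
  qual <- logical(nrow(stats))
  for (cn in unique(stats$chrom)) {
    i <- which(stats$chrom == cn)
    s <- sig[i]
    n <- length(s)
    if (n >= 3L) {
      q <- s & c(FALSE, s[-n]) & c(s[-1], FALSE)
    } else {
      q <- rep(FALSE, n)
    }
    qual[i] <- q
  }
  stats$significant <- sig
  stats$qualifying <- qual
  stats
}

#' Merge flagged windows into peaks
#'
#' Each maximal run of consecutive significant windows that contains at
#' least one qualifying window becomes one peak spanning the whole run;
#' significant runs with no qualifying window (length <= 2, or longer runs
#' broken at chromosome ends) yield no peak. Peaks are disjoint and sorted.
#'
#' @param stats Flagged window-stats data.frame (`chrom`, `start`, `end`,
#'   `ip_count`, `pval`, `significant`, `qualifying`), windows in genomic
#'   order per chromosome.
#' @return data.frame of peaks: `chrom`, `start`, `end`, `n_windows`,
#'   `min_pval`, `summit` (midpoint of the window with the highest IP count;
#'   first such window on ties).
#' @export
merge_peaks <- function(stats) {
  need <- c("chrom", "start", "end", "pval", "significant", "qualifying")
  stopifnot(is.data.frame(stats), all(need %in% names(stats)))
  ip <- if ("ip_count" %in% names(stats)) stats$ip_count else -stats$pval
  peaks <- list()
  for (cn in unique(stats$chrom)) {
    i <- which(stats$chrom == cn)
    s <- stats$significant[i]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- i[starts[j]:ends[j]]
      if (!any(stats$qualifying[run])) next
      top <- run[which.max(ip[run])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = cn,
        start = stats$start[run[1L]],
        end = stats$end[run[length(run)]],
        n_windows = length(run),
        min_pval = min(stats$pval[run]),
        summit = (stats$start[top] + stats$end[top]) %/% 2L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(peaks)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      min_pval = numeric(), summit = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call ChIP-seq peaks with the windowed Poisson enrichment test
#'
#' The full caller: duplicate reads are removed, each read is extended to a
#' fragment in its 3' direction, fragments are counted in 50-bp genome
#' windows for IP and input, the input count is scaled by the ratio of
#' library totals (with a floor at the genome-wide mean normalized input per
#' window) to give the expected count lambda, each window is tested with the
#' Poisson upper tail P(X >= ip_count | lambda), windows with P below
#' `alpha` whose two neighbours are also below `alpha` qualify, and maximal
#' significant runs containing a qualifying window are merged into peaks.
#'
#' @param ip_reads,input_reads Aligned-read data.frames (`chrom`, `pos`,
#'   `strand`, `length`); both must be non-empty.
#' @param genome A `toy_genome`, or a named vector of chromosome lengths.
#' @param window Window width in bp (default 50).
#' @param ext Read extension in bp (default 150); see [extend_reads()].
#' @param alpha Per-window significance threshold (strict `<`; default
#'   1e-3).
#' @param lam_floor Minimum expected count per window, or `"auto"` (default)
#'   for the genome-wide mean normalized input count per window.
#' @param dedup Remove clonal duplicates first (default `TRUE`).
#' @param extend_mode Passed to [extend_reads()].
#' @param keep_window_stats Keep the per-window table in the result
#'   (default `TRUE`).
#' @return An object of class `peak_call` with elements `peaks` (see
#'   [merge_peaks()]), `window_stats` (per-window `chrom`, `start`, `end`,
#'   `ip_count`, `input_count`, `lam`, `pval`, `significant`, `qualifying`),
#'   `totals`, `lam_floor` (the effective value), and `params`. Methods:
#'   `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' g <- make_toy_genome(1, 100000, 0, seed = 1)
#' d <- spike_design(g, data.frame(chrom = "chr1", start = 40000,
#'                                 end = 40500),
#'                   enrichment = 20, depth = 2e5)
#' pc <- call_peaks(simulate_chip_library(g, d, seed = 1),
#'                  simulate_chip_library(g, d, is_input = TRUE, seed = 2),
#'                  g)
#' pc
#' @export
call_peaks <- function(ip_reads, input_reads, genome, window = 50L,
                       ext = 150L, alpha = 1e-3, lam_floor = "auto",
                       dedup = TRUE, extend_mode = c("fragment", "append"),
                       keep_window_stats = TRUE) {
  extend_mode <- match.arg(extend_mode)
  chrom_sizes <- if (inherits(genome, "toy_genome")) genome$chrom_sizes
                 else genome
  if (is.null(ip_reads) || !nrow(ip_reads)) {
    stop("IP library is empty", call. = FALSE)
  }
  if (is.null(input_reads) || !nrow(input_reads)) {
    stop("input library is empty", call. = FALSE)
  }
  if (dedup) {
    ip_reads <- dedupe_reads(ip_reads)
    input_reads <- dedupe_reads(input_reads)
  }
  ip_total <- nrow(ip_reads)
  input_total <- nrow(input_reads)
  ip_frag <- extend_reads(ip_reads, chrom_sizes, ext, extend_mode)
  in_frag <- extend_reads(input_reads, chrom_sizes, ext, extend_mode)
  ip_counts <- count_windows(ip_frag, chrom_sizes, window)
  in_counts <- count_windows(in_frag, chrom_sizes, window)

  ratio <- ip_total / input_total
  if (identical(lam_floor, "auto")) {
    lam_floor <- mean(unlist(in_counts, use.names = FALSE)) * ratio
  }
  stats <- do.call(rbind, lapply(names(chrom_sizes), function(cn) {
    n_win <- length(ip_counts[[cn]])
    start <- (seq_len(n_win) - 1L) * as.integer(window)
    data.frame(chrom = cn, start = start,
               end = pmin(start + as.integer(window),
                          as.integer(chrom_sizes[[cn]])),
               ip_count = ip_counts[[cn]], input_count = in_counts[[cn]],
               stringsAsFactors = FALSE)
  }))
  stats$lam <- normalize_input(stats$input_count, ip_total, input_total,
                               lam_floor)
  stats$pval <- poisson_upper_tail(stats$ip_count, stats$lam)
  stats <- flag_windows(stats, alpha)
  peaks <- merge_peaks(stats)
  structure(list(
    peaks = peaks,
    window_stats = if (keep_window_stats) stats else NULL,
    totals = c(ip = ip_total, input = input_total),
    lam_floor = lam_floor,
    params = list(window = as.integer(window), ext = as.integer(ext),
                  alpha = alpha, dedup = dedup,
                  extend_mode = extend_mode)),
    class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf(
    "peak_call: %d peak(s) | IP %d reads, input %d reads (deduped: %s)\n",
    nrow(x$peaks), x$totals[["ip"]], x$totals[["input"]],
    if (x$params$dedup) "yes" else "no"))
  cat(sprintf(
    "  window %d bp, ext %d bp (%s), alpha %.3g, lambda floor %.4g\n",
    x$params$window, x$params$ext, x$params$extend_mode, x$params$alpha,
    x$lam_floor))
  if (nrow(x$peaks)) {
    print(utils::head(x$peaks, 5L))
    if (nrow(x$peaks) > 5L) cat(sprintf("  ... %d more\n",
                                        nrow(x$peaks) - 5L))
  }
  invisible(x)
}

#' @export
summary.peak_call <- function(object, ...) {
  p <- object$peaks
  s <- object$window_stats
  out <- list(
    n_peaks = nrow(p),
    total_peak_bp = if (nrow(p)) sum(p$end - p$start) else 0L,
    median_width = if (nrow(p)) stats::median(p$end - p$start) else NA_real_,
    min_pval = if (nrow(p)) min(p$min_pval) else NA_real_,
    frac_significant_windows = if (!is.null(s)) mean(s$significant)
                               else NA_real_,
    totals = object$totals, params = object$params,
    lam_floor = object$lam_floor)
  class(out) <- "summary.peak_call"
  out
}

#' @export
print.summary.peak_call <- function(x, ...) {
  cat(sprintf("Peak call summary: %d peaks spanning %d bp\n",
              x$n_peaks, x$total_peak_bp))
  cat(sprintf("  median width %.0f bp, best P-value %.3g\n",
              x$median_width, x$min_pval))
  if (!is.na(x$frac_significant_windows)) {
    cat(sprintf("  significant windows: %.4f%% of genome\n",
                100 * x$frac_significant_windows))
  }
  cat(sprintf("  library totals: IP %d, input %d; lambda floor %.4g\n",
              x$totals[["ip"]], x$totals[["input"]], x$lam_floor))
  invisible(x)
}

#' @export
as.data.frame.peak_call <- function(x, ...) x$peaks

#' Plot the per-window enrichment track of a peak call
#'
#' Draws -log10(P) per window along one chromosome with called peaks marked
#' under the axis.
#'
#' @param x A `peak_call` (must retain window stats).
#' @param chrom Chromosome to plot (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.peak_call <- function(x, chrom = NULL, ...) {
  s <- x$window_stats
  if (is.null(s)) stop("peak_call was built with keep_window_stats = FALSE")
  if (is.null(chrom)) chrom <- s$chrom[1L]
  s <- s[s$chrom == chrom, , drop = FALSE]
  y <- -log10(pmax(s$pval, 1e-300))
  graphics::plot(s$start, y, type = "h", col = "grey40",
                 xlab = sprintf("%s position (bp)", chrom),
                 ylab = expression(-log[10] ~ italic(P)), ...)
  graphics::abline(h = -log10(x$params$alpha), lty = 2, col = "red3")
  p <- x$peaks[x$peaks$chrom == chrom, , drop = FALSE]
  if (nrow(p)) {
    graphics::rect(p$start, -max(y) * 0.04, p$end, 0, col = "red3",
                   border = NA)
  }
  invisible(x)
}
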