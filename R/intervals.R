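#' Intersect two interval sets
#'
#' Returns every pair of intervals (one from `a`, one from `b`) sharing at
#' least 1 bp, together with the overlap interval. Coordinates are 0-based
#' half-open in both input and output.
#'
#' @param a,b Interval data.frames (`chrom`, `start`, `end`).
#' @return data.frame with one row per overlapping pair: `a_idx`, `b_idx`
#'   (row indices into `a` and `b`), `chrom`, `start`, `end` of the overlap,
#'   sorted by chromosome and overlap start.
#' @examples
#' interval_intersect(data.frame(chrom = "chr1", start = 100, end = 200),
#'                    data.frame(chrom = "chr1", start = 150, end = 250))
#' @export
interval_intersect <- function(a, b) {
  a <- check_intervals(a, "a")
  b <- check_intervals(b, "b")
  if (!nrow(a) || !nrow(b)) {
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- list()
  for (cn in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == cn)
    ib <- which(b$chrom == cn)
    hits <- IRanges::findOverlaps(as_iranges0(a$start[ia], a$end[ia]),
                                  as_iranges0(b$start[ib], b$end[ib]))
    if (!length(hits)) next
    qi <- ia[S4Vectors::queryHits(hits)]
    si <- ib[S4Vectors::subjectHits(hits)]
    res[[cn]] <- data.frame(
      a_idx = qi, b_idx = si, chrom = cn,
      start = pmax(a$start[qi], b$start[si]),
      end = pmin(a$end[qi], b$end[si]),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$end, out$a_idx, out$b_idx), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify peaks by distance to the nearest TSS
#'
#' Each peak's midpoint is compared with the nearest transcription start
#' site on its chromosome. Peaks within 5 kb are proximal (promoter-like),
#' peaks between 5 and 500 kb are distal (enhancer-like), and anything
#' further is far; both boundaries are inclusive.
#'
#' @param peaks Interval data.frame (`chrom`, `start`, `end`).
#' @param tss TSS data.frame (`chrom`, `pos`).
#' @param proximal_max,distal_max Class boundaries in bp (defaults 5000 and
#'   500000, both inclusive).
#' @return data.frame with one row per peak: `label` (factor proximal /
#'   distal / far) and `distance` (bp, unsigned; `NA` when the peak's
#'   chromosome carries no TSS, in which case the label is far).
#' @examples
#' classify_tss_distance(data.frame(chrom = "chr1", start = 7000,
#'                                  end = 8000),
#'                       data.frame(chrom = "chr1", pos = 4500))
#' @export
classify_tss_distance <- function(peaks, tss, proximal_max = 5000,
                                  distal_max = 500000) {
  peaks <- check_intervals(peaks, "peaks")
  if (!is.data.frame(tss) || !all(c("chrom", "pos") %in% names(tss))) {
    stop("'tss' must be a data.frame with chrom/pos", call. = FALSE)
  }
  mid <- (peaks$start + peaks$end) %/% 2L
  distance <- rep(NA_real_, nrow(peaks))
  for (cn in unique(peaks$chrom)) {
    i <- which(peaks$chrom == cn)
    p <- sort(tss$pos[tss$chrom == cn])
    if (!length(p)) next
    j <- findInterval(mid[i], p)
    lo <- ifelse(j >= 1L, p[pmax(j, 1L)], NA_real_)
    hi <- ifelse(j < length(p), p[pmin(j + 1L, length(p))], NA_real_)
    distance[i] <- pmin(abs(mid[i] - lo), abs(mid[i] - hi), na.rm = TRUE)
  }
  no_tss <- is.na(distance)
  if (any(no_tss)) {
    message(sum(no_tss), " peak(s) on chromosomes without TSS: classed far")
  }
  label <- ifelse(no_tss, "far",
                  ifelse(distance <= proximal_max, "proximal",
                         ifelse(distance <= distal_max, "distal", "far")))
  data.frame(label = factor(label, levels = c("proximal", "distal", "far")),
             distance = distance)
}

#' Build basal-plus-extension gene regulatory domains
#'
#' Each gene receives a basal domain around its TSS (`basal_up` bp upstream,
#' `basal_down` bp downstream, strand-aware), then the domain is extended in
#' both directions up to the nearer of the neighbouring gene's basal domain
#' or `max_ext` bp from the TSS. Extension never shrinks a basal domain, so
#' neighbouring regulatory domains may overlap. This is a local
#' approximation of the GREAT basal-plus-extension association rule (its GO
#' enrichment half is not reproduced).
#'
#' @param tss TSS data.frame (`chrom`, `pos`, `strand`, `gene_id`).
#' @param basal_up,basal_down Basal domain extent upstream/downstream of the
#'   TSS in bp (defaults 5000 and 1000).
#' @param max_ext Maximum extension from the TSS in bp (default 1e6).
#' @param chrom_sizes Optional named vector for clipping at chromosome ends.
#' @return data.frame of domains: `chrom`, `start`, `end`, `gene_id`.
#' @export
gene_regulatory_domains <- function(tss, basal_up = 5000, basal_down = 1000,
                                    max_ext = 1e6, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "pos", "strand", "gene_id") %in% names(tss)))
  if (!all(tss$strand %in% c("+", "-"))) {
    stop("TSS records need '+'/'-' strands for basal domains",
         call. = FALSE)
  }
  plus <- tss$strand == "+"
  basal_start <- ifelse(plus, tss$pos - basal_up, tss$pos - basal_down)
  basal_end <- ifelse(plus, tss$pos + basal_down, tss$pos + basal_up)
  out <- lapply(unique(tss$chrom), function(cn) {
    i <- which(tss$chrom == cn)
    i <- i[order(tss$pos[i])]
    bs <- basal_start[i]; be <- basal_end[i]; pos <- tss$pos[i]
    n <- length(i)
    # running extremes handle out-of-order basal edges of nearby genes
    prev_end <- c(0, cummax(be))[seq_len(n)]
    next_start <- rev(c(Inf, cummin(rev(bs)))[seq_len(n)])
    lim <- if (!is.null(chrom_sizes)) chrom_sizes[[cn]] else Inf
    start <- pmin(bs, pmax(pos - max_ext, prev_end))
    end <- pmax(be, pmin(pos + max_ext, next_start))
    data.frame(chrom = cn, start = pmax(start, 0),
               end = pmin(end, lim), gene_id = tss$gene_id[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assign peaks to genes by regulatory domain
#'
#' A peak is assigned to every gene whose basal-plus-extension regulatory
#' domain (see [gene_regulatory_domains()]) contains the peak's midpoint; a
#' peak may therefore map to zero, one or several genes.
#'
#' @param peaks Interval data.frame.
#' @param tss TSS data.frame (`chrom`, `pos`, `strand`, `gene_id`).
#' @inheritParams gene_regulatory_domains
#' @return data.frame with columns `peak_idx` (row index into `peaks`) and
#'   `gene_id`, one row per assignment.
#' @examples
#' tss <- data.frame(chrom = "chr1", pos = 50000, strand = "+",
#'                   gene_id = "g1")
#' assign_genes(data.frame(chrom = "chr1", start = 47500, end = 48500), tss)
#' @export
assign_genes <- function(peaks, tss, basal_up = 5000, basal_down = 1000,
                         max_ext = 1e6, chrom_sizes = NULL) {
  peaks <- check_intervals(peaks, "peaks")
  dom <- gene_regulatory_domains(tss, basal_up, basal_down, max_ext,
                                 chrom_sizes)
  mid <- (peaks$start + peaks$end) %/% 2L
  res <- list()
  for (cn in unique(peaks$chrom)) {
    i <- which(peaks$chrom == cn)
    d <- dom[dom$chrom == cn, , drop = FALSE]
    if (!nrow(d)) next
    for (k in i) {
      hit <- d$start <= mid[k] & mid[k] < d$end
      if (any(hit)) {
        res[[length(res) + 1L]] <- data.frame(
          peak_idx = k, gene_id = d$gene_id[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(peak_idx = integer(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count overlap membership of one peak set against one or two others
#'
#' Classifies every region of the first-named set by which of the other sets
#' it overlaps (>= 1 bp), giving the cell counts of a 2- or 3-set Venn
#' diagram from the first set's point of view. Counts sum to the size of the
#' first set.
#'
#' @param sets Named list of 2 or 3 interval data.frames; each must be
#'   internally non-overlapping (merge first, e.g. with
#'   [build_universe()]).
#' @return Named integer vector of counts, one per membership category
#'   (e.g. `A_only`, `A&B` for two sets).
#' @examples
#' A <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150))
#' B <- data.frame(chrom = "chr1", start = 120, end = 200)
#' overlap_counts(list(A = A, B = B))
#' @export
overlap_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L ||
      is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("'sets' must be a named list of 2 or 3 interval sets",
         call. = FALSE)
  }
  nms <- names(sets)
  sets <- lapply(nms, function(nm) {
    x <- check_intervals(sets[[nm]], nm)
    if (nrow(x) > 1L) {
      xs <- sort_intervals(x)
      self_ov <- any(unlist(lapply(split(seq_len(nrow(xs)), xs$chrom),
                                   function(i) {
                                     if (length(i) < 2L) return(FALSE)
                                     xs$start[i][-1] < xs$end[i][-length(i)]
                                   })))
      if (self_ov) stop("set '", nm, "' has internal overlaps; merge first",
                        call. = FALSE)
    }
    x
  })
  names(sets) <- nms
  first <- sets[[1L]]
  others <- sets[-1L]
  # membership: for each region of the first set, which other sets touch it
  hits <- vapply(others, function(o) {
    h <- logical(nrow(first))
    if (!nrow(first) || !nrow(o)) return(h)
    ov <- interval_intersect(first, o)
    h[unique(ov$a_idx)] <- TRUE
    h
  }, logical(nrow(first)))
  hits <- matrix(hits, nrow = nrow(first),
                 dimnames = list(NULL, names(others)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
  names(combos) <- names(others)
  labels <- apply(combos, 1L, function(row) {
    inset <- names(others)[as.logical(row)]
    if (!length(inset)) paste0(nms[1L], "_only")
    else paste(c(nms[1L], inset), collapse = "&")
  })
  counts <- apply(combos, 1L, function(row) {
    sum(apply(hits, 1L, function(h) all(h == as.logical(row))))
  })
  stats::setNames(as.integer(counts), labels)
}

#' Mean signal metaprofile around anchor points
#'
#' For every anchor, the window `[center - flank, center + flank)` is split
#' into `n_bins` equal bins; the profile value of bin b is the mean over
#' anchors of the mean per-bp signal in that bin. Anchors whose window runs
#' off a chromosome end are dropped (with a message).
#'
#' @param signal Named list of per-bp numeric vectors, one per chromosome
#'   (e.g. from [fragment_coverage()]).
#' @param anchors data.frame with columns `chrom` and `center` (0-based bp),
#'   typically peak summits or midpoints.
#' @param flank Half-width of the profiled window in bp.
#' @param n_bins Number of bins; `2 * flank` must be divisible by `n_bins`.
#' @return Numeric vector of length `n_bins` with attribute `offset`, the
#'   bin-center offsets from the anchor in bp.
#' @examples
#' sig <- list(chr1 = rep(1, 1000))
#' metaprofile(sig, data.frame(chrom = "chr1", center = 500),
#'             flank = 200, n_bins = 8)
#' @export
metaprofile <- function(signal, anchors, flank = 2000L, n_bins = 100L) {
  check_count(flank, "flank", min = 1L)
  check_count(n_bins, "n_bins", min = 1L)
  if ((2L * flank) %% n_bins != 0L) {
    stop("2 * flank must be divisible by n_bins", call. = FALSE)
  }
  if (!is.data.frame(anchors) ||
      !all(c("chrom", "center") %in% names(anchors)) || !nrow(anchors)) {
    stop("'anchors' must be a non-empty data.frame with chrom/center",
         call. = FALSE)
  }
  bw <- (2L * flank) %/% n_bins
  keep <- logical(nrow(anchors))
  for (k in seq_len(nrow(anchors))) {
    cn <- as.character(anchors$chrom[k])
    keep[k] <- cn %in% names(signal) &&
      anchors$center[k] - flank >= 0 &&
      anchors$center[k] + flank <= length(signal[[cn]])
  }
  if (!any(keep)) stop("no anchor window fits inside the genome",
                       call. = FALSE)
  if (any(!keep)) {
    message(sum(!keep), " anchor(s) truncated by chromosome edges: dropped")
  }
  anchors <- anchors[keep, , drop = FALSE]
  prof <- matrix(0, nrow = nrow(anchors), ncol = n_bins)
  for (k in seq_len(nrow(anchors))) {
    cn <- as.character(anchors$chrom[k])
    w <- signal[[cn]][(anchors$center[k] - flank + 1L):
                        (anchors$center[k] + flank)]
    prof[k, ] <- colMeans(matrix(w, nrow = bw))
  }
  out <- colMeans(prof)
  attr(out, "offset") <- -flank + (seq_len(n_bins) - 0.5) * bw
  out
}

#' Per-bp fragment coverage track
#'
#' Builds the per-bp coverage of a fragment set over a (toy-scale) genome,
#' the natural signal input for [metaprofile()].
#'
#' @param fragments Fragment data.frame (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of chromosome lengths (or a
#'   `toy_genome`).
#' @return Named list of numeric vectors, one per chromosome, element i
#'   giving the number of fragments covering base i - 1 (0-based).
#' @export
fragment_coverage <- function(fragments, chrom_sizes) {
  if (inherits(chrom_sizes, "toy_genome")) chrom_sizes <- chrom_sizes$chrom_sizes
  fragments <- check_intervals(fragments, "fragments")
  out <- lapply(names(chrom_sizes), function(cn) {
    L <- as.integer(chrom_sizes[[cn]])
    f <- fragments[fragments$chrom == cn, , drop = FALSE]
    if (!nrow(f)) return(numeric(L))
    delta <- numeric(L + 1L)
    s <- pmax(f$start, 0L) + 1L
    e <- pmin(f$end, L) + 1L
    ok <- s <= L & e > 1L
    tf <- tabulate(s[ok], nbins = L + 1L)
    tl <- tabulate(e[ok], nbins = L + 1L)
    cumsum(tf - tl)[seq_len(L)]
  })
  names(out) <- names(chrom_sizes)
  out
}
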