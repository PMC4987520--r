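#' Describe spiked enrichment regions for a simulated ChIP experiment
#'
#' A spike design records where binding signal is placed on a toy genome and
#' how strong it is: a set of disjoint regions, a fold enrichment per region,
#' the per-bp background read rate and the target library depth. Exactly one
#' of `background_rate` and `depth` may be omitted; the other is derived so
#' that the expected total read count of an IP library equals `depth`:
#' `depth = background_rate * (G + sum((enrichment - 1) * width))` with `G`
#' the genome length.
#'
#' @param genome A `toy_genome`.
#' @param regions data.frame of enriched regions (`chrom`, `start`, `end`,
#'   0-based half-open), or `NULL`/empty for a pure-background design.
#' @param enrichment Fold enrichment per region (recycled), each > 1.
#' @param background_rate Expected background read starts per bp.
#' @param depth Expected total reads per library.
#' @param read_length Read length in bp (default 50, single-end).
#' @param fragment_length Footprint of the sequenced fragment in bp (default
#'   150). Enriched reads are placed so their fragment lies inside the spiked
#'   region; this is also the natural read-extension length downstream.
#' @return An object of class `spike_design`.
#' @examples
#' g <- make_toy_genome(1, 100000, 0, seed = 1)
#' d <- spike_design(g, data.frame(chrom = "chr1", start = 4000, end = 4500),
#'                   enrichment = 20, depth = 2e5)
#' d$background_rate
#' @export
spike_design <- function(genome, regions = NULL, enrichment = numeric(),
                         background_rate = NULL, depth = NULL,
                         read_length = 50L, fragment_length = 150L) {
  stopifnot(inherits(genome, "toy_genome"))
  if (is.null(regions) || !nrow(as.data.frame(regions))) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
    enrichment <- numeric()
  } else {
    regions <- sort_intervals(check_intervals(regions, "regions"))
    rownames(regions) <- NULL
    enrichment <- rep_len(enrichment, nrow(regions))
    if (any(enrichment <= 1)) {
      stop("'enrichment' must be > 1 for every region", call. = FALSE)
    }
    bad <- !(regions$chrom %in% names(genome$chrom_sizes)) |
      regions$end > genome$chrom_sizes[regions$chrom]
    if (any(bad)) {
      stop("spike region(s) outside genome bounds: ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
    ov <- unsplit(lapply(split(seq_len(nrow(regions)), regions$chrom),
                         function(i) {
                           s <- regions$start[i]; e <- regions$end[i]
                           c(FALSE, s[-1] < e[-length(e)])[seq_along(i)]
                         }), regions$chrom)
    if (any(ov)) stop("spike regions overlap after sorting", call. = FALSE)
  }
  check_count(read_length, "read_length", min = 1L)
  check_count(fragment_length, "fragment_length", min = 1L)
  G <- sum(as.numeric(genome$chrom_sizes))
  mass <- G + sum((enrichment - 1) * (regions$end - regions$start))
  if (is.null(background_rate) && is.null(depth)) {
    stop("supply at least one of 'background_rate' and 'depth'",
         call. = FALSE)
  }
  if (is.null(depth)) depth <- background_rate * mass
  if (is.null(background_rate)) background_rate <- depth / mass
  if (background_rate <= 0 || depth < 0) {
    stop("'background_rate' must be > 0 and 'depth' >= 0", call. = FALSE)
  }
  structure(list(regions = regions, enrichment = enrichment,
                 background_rate = background_rate, depth = depth,
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length)),
            class = "spike_design")
}

#' Simulate an aligned ChIP-seq library
#'
#' Reads are placed directly as alignment coordinates (no sequence, no
#' mapper). The background is homogeneous: read starts fall uniformly over
#' the genome, strands are random, and the total read count is Poisson with
#' mean `design$depth`, so it matches the null model of the window-based
#' Poisson enrichment test. For an IP library (`is_input = FALSE`) the
#' expected read mass inside each spiked region is multiplied by that
#' region's fold enrichment; the extra enriched reads are placed so that
#' their `fragment_length`-bp fragment lies wholly within the region (the
#' region is the footprint of the bound locus), which leaves the mean read
#' start density across the region at enrichment times background. Input
#' libraries ignore the spikes entirely.
#'
#' @param genome A `toy_genome`.
#' @param design A [spike_design()].
#' @param is_input If `TRUE`, simulate a non-enriched input/control library.
#' @param seed Integer seed; same arguments and seed give identical output.
#' @return A data.frame of aligned reads with columns `chrom`, `pos` (0-based
#'   leftmost coordinate), `strand` (`+`/`-`) and `length`, sorted by
#'   position.
#' @examples
#' g <- make_toy_genome(1, 100000, 0, seed = 1)
#' d <- spike_design(g, data.frame(chrom = "chr1", start = 4000, end = 4500),
#'                   enrichment = 20, depth = 50000)
#' ip <- simulate_chip_library(g, d, seed = 2)
#' nrow(ip)
#' @export
simulate_chip_library <- function(genome, design, is_input = FALSE,
                                  seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"), inherits(design, "spike_design"))
  len <- design$read_length
  frag <- design$fragment_length
  regions <- design$regions
  enr <- if (is_input) rep(1, nrow(regions)) else design$enrichment
  G <- sum(as.numeric(genome$chrom_sizes))
  extra <- if (nrow(regions)) (enr - 1) * (regions$end - regions$start)
           else numeric()
  with_seed(seed, {
    n_total <- stats::rpois(1L, design$depth)
    if (n_total == 0L) {
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), length = integer(),
                        stringsAsFactors = FALSE))
    }
    # split reads between uniform background and per-region enriched excess
    p <- c(G, extra) / (G + sum(extra))
    comp <- sample.int(length(p), n_total, replace = TRUE, prob = p)
    n_bg <- sum(comp == 1L)
    # background: chromosome weighted by length, start uniform
    chrom <- character(n_total)
    pos <- integer(n_total)
    strand <- sample(c("+", "-"), n_total, replace = TRUE)
    if (n_bg) {
      ci <- sample.int(length(genome$chrom_sizes), n_bg, replace = TRUE,
                       prob = genome$chrom_sizes)
      chrom[comp == 1L] <- names(genome$chrom_sizes)[ci]
      hi <- pmax(genome$chrom_sizes[ci] - len, 1L)
      pos[comp == 1L] <- as.integer(floor(stats::runif(n_bg) * hi))
    }
    # enriched excess: fragment contained in the region when it fits
    for (r in seq_len(nrow(regions))) {
      idx <- which(comp == r + 1L)
      if (!length(idx)) next
      rs <- regions$start[r]; re <- regions$end[r]
      w <- re - rs
      chrom[idx] <- regions$chrom[r]
      plus <- strand[idx] == "+"
      if (w >= frag) {
        # + read: fragment [pos, pos+frag) inside; - read: fragment
        # [pos+len-frag, pos+len) inside
        fs <- rs + as.integer(floor(stats::runif(length(idx)) *
                                      (w - frag + 1L)))
        pos[idx] <- ifelse(plus, fs, fs + frag - len)
      } else {
        pos[idx] <- ifelse(plus, rs, re - len)
      }
    }
    out <- data.frame(chrom = chrom, pos = pmax(pos, 0L), strand = strand,
                      length = len, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a two-condition ATAC-seq region count matrix
#'
#' Builds a universe of `n_regions` disjoint regions on a virtual
#' chromosome and draws Poisson fragment counts for `n_reps` replicate
#' libraries per condition. A random subset of `n_differential` regions is
#' truly differential: its condition-A mean is `fold * base_mean` while its
#' condition-B mean stays at `base_mean`; all other regions have mean
#' `base_mean` in both conditions. Truth labels are returned alongside the
#' counts so the differential-accessibility decision rule can be scored.
#'
#' @param n_regions Number of regions.
#' @param n_differential Number of truly differential regions
#'   (`<= n_regions`).
#' @param fold True fold change of differential regions (>= 1).
#' @param base_mean Expected fragment count per region per library.
#' @param seed Integer seed.
#' @param n_reps Replicate libraries per condition (default 2).
#' @param region_width Width of each simulated region in bp (default 500).
#' @return A `region_counts` object (see [count_fragments()]) with an extra
#'   element `truth`, a logical vector marking the truly differential
#'   regions.
#' @examples
#' rc <- simulate_atac_counts(100, 10, fold = 8, base_mean = 200, seed = 5)
#' sum(rc$truth)
#' @export
simulate_atac_counts <- function(n_regions, n_differential, fold, base_mean,
                                 seed = NULL, n_reps = 2L,
                                 region_width = 500L) {
  check_count(n_regions, "n_regions", min = 1L)
  check_count(n_differential, "n_differential", min = 0L)
  if (n_differential > n_regions) {
    stop("'n_differential' must be <= 'n_regions'", call. = FALSE)
  }
  if (!is.numeric(fold) || length(fold) != 1L || fold < 1) {
    stop("'fold' must be a single value >= 1", call. = FALSE)
  }
  if (!is.numeric(base_mean) || base_mean <= 0) {
    stop("'base_mean' must be positive", call. = FALSE)
  }
  check_count(n_reps, "n_reps", min = 1L)
  gap <- region_width
  regions <- data.frame(
    chrom = "chr1",
    start = (seq_len(n_regions) - 1L) * (region_width + gap),
    end = (seq_len(n_regions) - 1L) * (region_width + gap) + region_width,
    stringsAsFactors = FALSE)
  with_seed(seed, {
    truth <- rep(FALSE, n_regions)
    if (fold > 1 && n_differential > 0L) {
      truth[sample.int(n_regions, n_differential)] <- TRUE
    }
    mean_a <- ifelse(truth, fold * base_mean, base_mean)
    mean_b <- rep(base_mean, n_regions)
    counts <- cbind(
      matrix(stats::rpois(n_regions * n_reps, mean_a), ncol = n_reps),
      matrix(stats::rpois(n_regions * n_reps, mean_b), ncol = n_reps))
    colnames(counts) <- c(paste0("A", seq_len(n_reps)),
                          paste0("B", seq_len(n_reps)))
    rc <- new_region_counts(regions, counts,
                            condition = rep(c("A", "B"), each = n_reps))
    rc$truth <- truth
    rc
  })
}

#' Simulate a qPCR cycle-threshold table for Ig rearrangement assays
#'
#' Inverts the 2^deltaCt quantification model: given a true rearrangement
#' frequency `f` and a reference Actb cycle threshold, the Ig target's Ct is
#' `ct_actb - log2(f)` plus Gaussian measurement noise, so that
#' [rearrangement_frequency()] recovers `f` exactly when `noise_sd = 0`.
#'
#' @param true_freqs Numeric vector of true frequencies, each in (0, 1].
#' @param ct_actb Reference-gene cycle threshold (cycles; default 20).
#' @param noise_sd Gaussian noise s.d. on the Ig Ct, in cycles (default 0).
#' @param seed Integer seed.
#' @param target Target label for the Ig rows (default `"Ig_kappa"`).
#' @param groups Optional group label per sample (default `"control"`).
#' @return A long-format Ct table: data.frame with columns `sample_id`,
#'   `group`, `target`, `ct`, two rows (Actb + target) per sample.
#' @examples
#' ct <- simulate_ct_table(c(1, 0.25), ct_actb = 20)
#' subset(ct, target != "Actb")$ct   # 20, 22
#' @export
simulate_ct_table <- function(true_freqs, ct_actb = 20, noise_sd = 0,
                              seed = NULL, target = "Ig_kappa",
                              groups = NULL) {
  if (!length(true_freqs) || any(!is.finite(true_freqs)) ||
      any(true_freqs <= 0 | true_freqs > 1)) {
    stop("'true_freqs' must all lie in (0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  n <- length(true_freqs)
  if (is.null(groups)) groups <- rep("control", n)
  groups <- rep_len(as.character(groups), n)
  sample_id <- sprintf("s%03d", seq_len(n))
  ct_ig <- with_seed(seed, {
    ct_actb - log2(true_freqs) + stats::rnorm(n, 0, noise_sd)
  })
  out <- data.frame(
    sample_id = rep(sample_id, each = 2L),
    group = rep(groups, each = 2L),
    target = rep(c("Actb", target), n),
    ct = as.vector(rbind(rep(ct_actb, n), ct_ig)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate comet-assay tail moments with known outliers
#'
#' Non-outlier cells draw tail moments from a tight unimodal distribution,
#' Normal(`base_scale`, 0.2 * `base_scale`) truncated at zero; outlier cells
#' are shifted upward by `outlier_shift`. Truth labels are returned so the
#' MAD-based outlier classifier can be scored against them.
#'
#' @param n Number of cells.
#' @param outlier_frac Fraction of cells that are true outliers, in [0, 1];
#'   `round(n * outlier_frac)` cells are labelled.
#' @param base_scale Location of the non-outlier distribution (tail-moment
#'   units; default 10).
#' @param outlier_shift Upward shift of outlier cells (same units;
#'   default 100).
#' @param seed Integer seed.
#' @return data.frame with columns `cell_id`, `tail_moment`, `is_outlier`.
#' @examples
#' tm <- simulate_tail_moments(1000, 0.1, seed = 1)
#' sum(tm$is_outlier)
#' @export
simulate_tail_moments <- function(n, outlier_frac, base_scale = 10,
                                  outlier_shift = 100, seed = NULL) {
  check_count(n, "n", min = 1L)
  check_fraction(outlier_frac, "outlier_frac")
  if (base_scale <= 0) stop("'base_scale' must be positive", call. = FALSE)
  n_out <- round(n * outlier_frac)
  with_seed(seed, {
    is_outlier <- rep(FALSE, n)
    if (n_out > 0L) is_outlier[sample.int(n, n_out)] <- TRUE
    tm <- pmax(stats::rnorm(n, base_scale, 0.2 * base_scale), 0)
    tm[is_outlier] <- tm[is_outlier] + outlier_shift
    data.frame(cell_id = sprintf("cell%04d", seq_len(n)),
               tail_moment = tm, is_outlier = is_outlier,
               stringsAsFactors = FALSE)
  })
}
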