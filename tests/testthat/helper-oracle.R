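# Independent brute-force oracles. Everything here recomputes results from
# first principles (direct PMF summation, per-base membership arrays,
# window-by-window loops) without touching the package's vectorized code
# paths, so agreement is evidence and not tautology.

# P(X >= k) for X ~ Poisson(lam) by direct PMF summation (log-space to
# survive large lam).
oracle_pois_upper <- function(k, lam) {
  if (k <= 0) return(1)
  if (lam == 0) return(0)
  j <- 0:(k - 1)
  logpmf <- -lam + j * log(lam) - lgamma(j + 1)
  m <- max(logpmf)
  lower <- exp(m) * sum(exp(logpmf - m))
  max(0, 1 - lower)
}

# Full windowed peak caller, loop-based.
oracle_call_peaks <- function(ip_reads, input_reads, chrom_sizes,
                              window = 50, ext = 150, alpha = 1e-3) {
  dedupe <- function(r) {
    key <- paste(r$chrom, r$pos, r$strand, sep = "/")
    r[match(unique(key), key), , drop = FALSE]
  }
  ip <- dedupe(ip_reads)
  input <- dedupe(input_reads)
  frag <- function(r, cn, L) {
    rr <- r[r$chrom == cn, , drop = FALSE]
    n <- nrow(rr)
    s <- numeric(n); e <- numeric(n)
    for (i in seq_len(n)) {
      if (rr$strand[i] == "+") {
        s[i] <- rr$pos[i]; e[i] <- rr$pos[i] + ext
      } else {
        s[i] <- rr$pos[i] + rr$length[i] - ext
        e[i] <- rr$pos[i] + rr$length[i]
      }
    }
    cbind(pmax(s, 0), pmin(e, L))
  }
  wcount <- function(fr, n_win) {
    counts <- integer(n_win)
    for (i in seq_len(nrow(fr))) {
      first <- fr[i, 1] %/% window
      last <- (fr[i, 2] - 1) %/% window
      for (w in first:last) {
        if (w >= 0 && w < n_win) counts[w + 1] <- counts[w + 1] + 1L
      }
    }
    counts
  }
  ip_c <- list(); in_c <- list()
  for (cn in names(chrom_sizes)) {
    n_win <- ceiling(chrom_sizes[[cn]] / window)
    ip_c[[cn]] <- wcount(frag(ip, cn, chrom_sizes[[cn]]), n_win)
    in_c[[cn]] <- wcount(frag(input, cn, chrom_sizes[[cn]]), n_win)
  }
  ratio <- nrow(ip) / nrow(input)
  all_in <- unlist(in_c, use.names = FALSE)
  floor_lam <- sum(all_in) / length(all_in) * ratio
  peaks <- NULL
  for (cn in names(chrom_sizes)) {
    k <- ip_c[[cn]]
    lam <- pmax(in_c[[cn]] * ratio, floor_lam)
    n <- length(k)
    pv <- numeric(n)
    for (i in seq_len(n)) pv[i] <- oracle_pois_upper(k[i], lam[i])
    sig <- pv < alpha
    qual <- rep(FALSE, n)
    if (n >= 3) {
      for (i in 2:(n - 1)) qual[i] <- sig[i - 1] && sig[i] && sig[i + 1]
    }
    i <- 1
    while (i <= n) {
      if (sig[i]) {
        j <- i
        while (j < n && sig[j + 1]) j <- j + 1
        if (any(qual[i:j])) {
          peaks <- rbind(peaks, data.frame(
            chrom = cn, start = (i - 1) * window,
            end = min(j * window, chrom_sizes[[cn]]),
            n_windows = j - i + 1, stringsAsFactors = FALSE))
        }
        i <- j + 1
      } else i <- i + 1
    }
  }
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), n_windows = integer(),
                        stringsAsFactors = FALSE)
  }
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

# All overlapping pairs by exhaustive pairwise comparison.
oracle_intersect <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        s <- max(a$start[i], b$start[j])
        e <- min(a$end[i], b$end[j])
        if (s < e) out <- rbind(out, data.frame(
          a_idx = i, b_idx = j, chrom = a$chrom[i], start = s, end = e,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start, out$end, out$a_idx, out$b_idx), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Union of two interval sets from a per-base membership array
# (chromosomes must fit in memory, so <= 1e4 bp in tests).
oracle_union <- function(a, b, chrom_len) {
  all <- rbind(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")])
  out <- NULL
  for (cn in sort(unique(all$chrom))) {
    member <- logical(chrom_len)
    x <- all[all$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(x))) {
      member[(x$start[i] + 1):x$end[i]] <- TRUE
    }
    r <- rle(member)
    pos <- cumsum(c(0, r$lengths))
    for (j in which(r$values)) {
      out <- rbind(out, data.frame(chrom = cn, start = pos[j],
                                   end = pos[j + 1],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# Gene regulatory domains per the documented basal-plus-extension rule,
# computed gene by gene against all neighbours.
oracle_domains <- function(tss, basal_up = 5000, basal_down = 1000,
                           max_ext = 1e6) {
  n <- nrow(tss)
  out <- NULL
  for (i in seq_len(n)) {
    up <- if (tss$strand[i] == "+") basal_up else basal_down
    down <- if (tss$strand[i] == "+") basal_down else basal_up
    bs <- tss$pos[i] - up
    be <- tss$pos[i] + down
    prev_end <- 0
    next_start <- Inf
    for (j in seq_len(n)) {
      if (j == i || tss$chrom[j] != tss$chrom[i]) next
      upj <- if (tss$strand[j] == "+") basal_up else basal_down
      downj <- if (tss$strand[j] == "+") basal_down else basal_up
      bsj <- tss$pos[j] - upj
      bej <- tss$pos[j] + downj
      if (tss$pos[j] < tss$pos[i]) prev_end <- max(prev_end, bej)
      if (tss$pos[j] > tss$pos[i]) next_start <- min(next_start, bsj)
    }
    start <- min(bs, max(tss$pos[i] - max_ext, prev_end))
    end <- max(be, min(tss$pos[i] + max_ext, next_start))
    out <- rbind(out, data.frame(chrom = tss$chrom[i],
                                 start = max(start, 0), end = end,
                                 gene_id = tss$gene_id[i],
                                 stringsAsFactors = FALSE))
  }
  out
}

oracle_assign <- function(peaks, tss, ...) {
  dom <- oracle_domains(tss, ...)
  out <- NULL
  for (k in seq_len(nrow(peaks))) {
    mid <- (peaks$start[k] + peaks$end[k]) %/% 2
    for (d in seq_len(nrow(dom))) {
      if (dom$chrom[d] == peaks$chrom[k] && dom$start[d] <= mid &&
            mid < dom$end[d]) {
        out <- rbind(out, data.frame(peak_idx = k,
                                     gene_id = dom$gene_id[d],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(peak_idx = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

# Venn membership of the first set against the others, region by region.
oracle_overlap_counts <- function(sets) {
  first <- sets[[1]]
  others <- sets[-1]
  labels <- counts <- NULL
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
  res <- stats::setNames(integer(nrow(combos)), seq_len(nrow(combos)))
  overlaps_any <- function(iv, set) {
    for (j in seq_len(nrow(set))) {
      if (set$chrom[j] == iv$chrom && max(iv$start, set$start[j]) <
            min(iv$end, set$end[j])) return(TRUE)
    }
    FALSE
  }
  for (r in seq_len(nrow(combos))) {
    lab <- as.logical(combos[r, ])
    cnt <- 0L
    for (i in seq_len(nrow(first))) {
      h <- vapply(others, function(o)
        overlaps_any(first[i, , drop = FALSE], o), logical(1))
      if (all(h == lab)) cnt <- cnt + 1L
    }
    inset <- names(others)[lab]
    nm <- if (!length(inset)) paste0(names(sets)[1], "_only")
          else paste(c(names(sets)[1], inset), collapse = "&")
    names(res)[r] <- nm
    res[r] <- cnt
  }
  res
}

# fraction of spiked-region bases covered by peaks and of peak bases inside
# spiked regions, by direct coordinate arithmetic
interval_overlap_bp <- function(x, y) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      if (x$chrom[i] == y$chrom[j]) {
        total <- total +
          max(0, min(x$end[i], y$end[j]) - max(x$start[i], y$start[j]))
      }
    }
  }
  total
}
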