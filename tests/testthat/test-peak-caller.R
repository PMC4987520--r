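test_that("duplicate removal keys on chrom, position and strand", {
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), length = integer())
  expect_equal(nrow(dedupe_reads(empty)), 0L)
  r <- data.frame(chrom = "chr1", pos = c(100, 100, 100),
                  strand = c("+", "+", "-"), length = 50)
  expect_equal(nrow(dedupe_reads(r)), 2L)
  expect_equal(nrow(dedupe_reads(r, by_strand = FALSE)), 1L)
  uniq <- data.frame(chrom = "chr1", pos = c(5, 10, 15), strand = "+",
                     length = 50)
  expect_equal(dedupe_reads(uniq), uniq)
})

test_that("read extension replaces the read by a 3'-directed fragment", {
  cs <- c(chr1 = 100000)
  f <- extend_reads(data.frame(chrom = "chr1", pos = 100, strand = "+",
                               length = 50), cs, ext = 150)
  expect_equal(c(f$start, f$end), c(100, 250))
  f <- extend_reads(data.frame(chrom = "chr1", pos = 400, strand = "-",
                               length = 50), cs, ext = 150)
  expect_equal(c(f$start, f$end), c(300, 450))
  # clipping at the chromosome start
  f <- extend_reads(data.frame(chrom = "chr1", pos = 10, strand = "-",
                               length = 50), cs, ext = 150)
  expect_equal(c(f$start, f$end), c(0, 60))
  # append mode keeps the read and adds ext beyond its 3' end
  f <- extend_reads(data.frame(chrom = "chr1", pos = 100, strand = "+",
                               length = 50), cs, ext = 150,
                    mode = "append")
  expect_equal(c(f$start, f$end), c(100, 300))
  expect_error(extend_reads(data.frame(chrom = "chr1", pos = 1,
                                       strand = "?", length = 50), cs),
               "strand")
})

test_that("window counting increments every overlapped window", {
  cs <- c(chr1 = 500)
  cnt <- count_windows(data.frame(chrom = "chr1", start = 100, end = 250),
                       cs, window = 50)$chr1
  expect_equal(cnt, c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(count_windows(data.frame(chrom = character(),
                                        start = integer(),
                                        end = integer()), cs)$chr1,
               integer(10))
  cnt <- count_windows(data.frame(chrom = "chr1", start = 0, end = 50),
                       cs, window = 50)$chr1
  expect_equal(cnt, c(1, rep(0, 9)))
  # total assignments = sum over fragments of windows overlapped
  set.seed(42)
  fr <- data.frame(chrom = "chr1", start = s <- sample(0:400, 50),
                   end = s + sample(1:100, 50, replace = TRUE))
  fr$end <- pmin(fr$end, 500)
  cnt <- count_windows(fr, cs, window = 50)$chr1
  expect_equal(sum(cnt),
               sum((pmin(fr$end - 1, 499) %/% 50) - (fr$start %/% 50) + 1))
  expect_error(count_windows(data.frame(chrom = "chrX", start = 0,
                                        end = 10), cs), "unknown")
})

test_that("input normalization scales by library totals and floors lambda", {
  expect_equal(normalize_input(4, 1000, 500, 0), 8)
  expect_equal(normalize_input(7, 1200, 1200, 0), 7)
  expect_equal(normalize_input(0, 1000, 500, lam_floor = 0.8), 0.8)
  expect_error(normalize_input(1, 0, 10), "totals")
})

test_that("poisson upper tail matches PMF summation and is monotone", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(3, 0), 0)
  expect_equal(poisson_upper_tail(5, 1), 0.00365984682734371,
               tolerance = 1e-12)
  for (k in c(1, 3, 10, 40)) {
    for (lam in c(0.1, 1, 5, 40, 300)) {
      # absolute tolerance: the 1 - sum oracle carries ~1e-15 absolute error
      expect_lt(abs(poisson_upper_tail(k, lam) - oracle_pois_upper(k, lam)),
                1e-12)
    }
  }
  # non-decreasing in lam for fixed k; non-increasing in k for fixed lam
  lam_grid <- seq(0.1, 30, by = 0.5)
  expect_true(all(diff(poisson_upper_tail(rep(8, length(lam_grid)),
                                          lam_grid)) >= 0))
  expect_true(all(diff(poisson_upper_tail(0:40, rep(6, 41))) <= 0))
})

test_that("neighbour rule flags interior windows of significant runs", {
  s <- data.frame(chrom = "chr1", pval = c(0.5, 1e-4, 1e-4, 1e-4, 0.5))
  f <- flag_windows(s)
  expect_equal(f$significant, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(f$qualifying, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  f <- flag_windows(data.frame(chrom = "chr1", pval = rep(1, 6)))
  expect_false(any(f$significant) || any(f$qualifying))
  # two-window chromosome: significant but never qualifying
  f <- flag_windows(data.frame(chrom = "chr1", pval = c(1e-4, 1e-4)))
  expect_equal(f$qualifying, c(FALSE, FALSE))
  # ties at exactly alpha are not significant
  f <- flag_windows(data.frame(chrom = "chr1", pval = c(1e-3, 0.5e-3)))
  expect_equal(f$significant, c(FALSE, TRUE))
  # chromosome ends never qualify even inside a long significant run
  f <- flag_windows(data.frame(chrom = rep(c("chr1", "chr2"), each = 3),
                               pval = rep(1e-5, 6)))
  expect_equal(f$qualifying, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("peak merging spans maximal significant runs with a qualifying core", {
  mk <- function(pvals, w = 50) {
    n <- length(pvals)
    flag_windows(data.frame(chrom = "chr1", start = (0:(n - 1)) * w,
                            end = (1:n) * w, ip_count = seq_len(n),
                            pval = pvals))
  }
  p <- merge_peaks(mk(c(0.9, 1e-4, 1e-4, 1e-4, 0.9)))
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end, p$n_windows), c(50, 200, 3))
  # run of 2 cannot contain a qualifying window
  expect_equal(nrow(merge_peaks(mk(c(0.9, 1e-4, 1e-4, 0.9)))), 0L)
  # two runs split by one non-significant window give two peaks
  p <- merge_peaks(mk(c(1e-4, 1e-4, 1e-4, 0.9, 1e-4, 1e-4, 1e-4)))
  expect_equal(nrow(p), 2L)
  expect_equal(p$start, c(0, 200))
  # min_pval and summit are taken from the run
  st <- mk(c(0.9, 1e-4, 1e-6, 1e-4, 0.9))
  st$ip_count <- c(1, 5, 9, 4, 1)
  p <- merge_peaks(st)
  expect_equal(p$min_pval, 1e-6)
  expect_equal(p$summit, 125)
})

test_that("identical IP and input libraries yield no peaks", {
  g <- make_toy_genome(1, 100000, 0, seed = 2)
  d <- spike_design(g, NULL, depth = 20000)
  lib <- simulate_chip_library(g, d, seed = 5)
  pc <- call_peaks(lib, lib, g)
  expect_equal(nrow(pc$peaks), 0L)
})

test_that("a strong spike is recovered as exactly one overlapping peak", {
  g <- make_toy_genome(1, 100000, 0, seed = 3)
  reg <- data.frame(chrom = "chr1", start = 40000, end = 40500)
  d <- spike_design(g, reg, enrichment = 20, depth = 2e5)
  pc <- call_peaks(simulate_chip_library(g, d, seed = 7),
                   simulate_chip_library(g, d, is_input = TRUE, seed = 8),
                   g)
  expect_equal(nrow(pc$peaks), 1L)
  expect_gt(interval_overlap_bp(pc$peaks, reg), 0)
})

test_that("empty libraries raise errors naming the library", {
  g <- make_toy_genome(1, 100000, 0, seed = 1)
  d <- spike_design(g, NULL, depth = 1000)
  lib <- simulate_chip_library(g, d, seed = 1)
  none <- lib[0, ]
  expect_error(call_peaks(none, lib, g), "IP library is empty")
  expect_error(call_peaks(lib, none, g), "input library is empty")
})

test_that("the caller is deterministic in its inputs", {
  g <- make_toy_genome(1, 100000, 0, seed = 4)
  d <- spike_design(g, data.frame(chrom = "chr1", start = 10000,
                                  end = 10400),
                    enrichment = 15, depth = 50000)
  ip <- simulate_chip_library(g, d, seed = 1)
  input <- simulate_chip_library(g, d, is_input = TRUE, seed = 2)
  expect_identical(call_peaks(ip, input, g)$peaks,
                   call_peaks(ip, input, g)$peaks)
})

test_that("peak_call methods print, summarise and export", {
  g <- make_toy_genome(1, 100000, 0, seed = 3)
  d <- spike_design(g, data.frame(chrom = "chr1", start = 40000,
                                  end = 40500),
                    enrichment = 20, depth = 1e5)
  pc <- call_peaks(simulate_chip_library(g, d, seed = 7),
                   simulate_chip_library(g, d, is_input = TRUE, seed = 8),
                   g)
  expect_output(print(pc), "peak_call")
  expect_output(print(summary(pc)), "Peak call summary")
  expect_identical(as.data.frame(pc), pc$peaks)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(pc))
})
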