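test_that("toy genomes are deterministic, bounded and validated", {
  g0 <- make_toy_genome(1, 100000, 0, seed = 7)
  expect_equal(nrow(g0$tss), 0L)
  expect_identical(make_toy_genome(2, 50000, 10, seed = 3),
                   make_toy_genome(2, 50000, 10, seed = 3))
  g <- make_toy_genome(1, 100000, 50, seed = 1)
  expect_equal(nrow(g$tss), 50L)
  for (i in seq_len(nrow(g$tss))) {
    expect_true(g$tss$pos[i] >= 0 &&
                  g$tss$pos[i] < g$chrom_sizes[[g$tss$chrom[i]]])
  }
  expect_false(anyDuplicated(paste(g$tss$chrom, g$tss$pos)) > 0)
  expect_error(make_toy_genome(0, 100000, 1), "n_chrom")
  expect_error(make_toy_genome(1, 100, 1), "chrom_length")
})

test_that("chip library simulator honours depth, spikes and seeds", {
  g <- make_toy_genome(1, 100000, 0, seed = 1)
  # no spikes: IP and input are exchangeable under the same seed
  d0 <- spike_design(g, NULL, depth = 5000)
  expect_identical(simulate_chip_library(g, d0, is_input = FALSE, seed = 4),
                   simulate_chip_library(g, d0, is_input = TRUE, seed = 4))
  # zero depth -> empty library
  dz <- spike_design(g, NULL, depth = 0, background_rate = 1e-9)
  expect_equal(nrow(simulate_chip_library(g, dz, seed = 1)), 0L)
  # conservation: total reads within 4 sqrt(depth) of depth, several seeds
  d <- spike_design(g, data.frame(chrom = "chr1", start = 20000,
                                  end = 21000),
                    enrichment = 10, depth = 50000)
  for (s in 1:5) {
    n <- nrow(simulate_chip_library(g, d, seed = s))
    expect_lt(abs(n - 50000), 4 * sqrt(50000))
  }
  # bounds checking
  expect_error(spike_design(g, data.frame(chrom = "chr1", start = 99000,
                                          end = 101000),
                            enrichment = 5, depth = 1000), "bounds")
  expect_error(spike_design(g, data.frame(chrom = "chr9", start = 0,
                                          end = 100),
                            enrichment = 5, depth = 1000), "bounds")
})

test_that("mean read-start density in a spiked region matches enrichment", {
  g <- make_toy_genome(1, 100000, 0, seed = 1)
  reg <- data.frame(chrom = "chr1", start = 40000, end = 40500)
  d <- spike_design(g, reg, enrichment = 10, depth = 100000)
  ip <- simulate_chip_library(g, d, seed = 11)
  n <- nrow(ip)
  n_in <- sum(ip$pos >= reg$start & ip$pos < reg$end)
  # a read starts in the region with p = enr * w / weighted genome mass
  p_in <- 10 * 500 / (100000 + 9 * 500)
  expect_lt(abs(n_in - n * p_in), 3 * sqrt(n * p_in * (1 - p_in)))
  # and the implied in/out density ratio is ~10
  dens_ratio <- (n_in / 500) / ((n - n_in) / (100000 - 500))
  expect_gt(dens_ratio, 8.5)
  expect_lt(dens_ratio, 11.5)
})

test_that("atac count simulator labels and scales differential regions", {
  expect_true(all(!simulate_atac_counts(50, 10, fold = 1, base_mean = 100,
                                        seed = 1)$truth))
  rc <- simulate_atac_counts(100, 10, fold = 8, base_mean = 200, seed = 5)
  expect_equal(sum(rc$truth), 10L)
  expect_equal(dim(rc$counts), c(100L, 4L))
  # normalized library sums are equal after scaling
  expect_equal(diff(range(colSums(rc$normalized) /
                            mean(rc$library_totals))), 0, tolerance = 1e-9)
  # labelled regions have empirical A/B count ratio >= 4 in >= 9/10 cases
  ok <- 0L
  diffs <- which(rc$truth)
  for (i in diffs) {
    ratio <- sum(rc$counts[i, 1:2]) / sum(rc$counts[i, 3:4])
    if (ratio >= 4) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
  expect_error(simulate_atac_counts(10, 20, 2, 100, seed = 1),
               "n_differential")
})

test_that("ct table simulator inverts the 2^deltaCt model", {
  ct <- simulate_ct_table(1.0, ct_actb = 20, noise_sd = 0)
  expect_equal(ct$ct[ct$target != "Actb"], 20)
  ct <- simulate_ct_table(0.25, ct_actb = 20, noise_sd = 0)
  expect_equal(ct$ct[ct$target != "Actb"], 22)
  # noise-free round trip is the identity on frequencies
  freqs <- c(1, 0.5, 0.25, 0.01, 0.375)
  ct <- simulate_ct_table(freqs, ct_actb = 21.5, noise_sd = 0)
  actb <- ct$ct[ct$target == "Actb"]
  ig <- ct$ct[ct$target != "Actb"]
  expect_equal(rearrangement_frequency(actb, ig), freqs)
  expect_error(simulate_ct_table(c(0.5, 1.5)), "true_freqs")
  expect_error(simulate_ct_table(0), "true_freqs")
})

test_that("tail-moment simulator produces the requested outlier structure", {
  expect_true(all(!simulate_tail_moments(100, 0, seed = 1)$is_outlier))
  tm <- simulate_tail_moments(1000, 0.1, seed = 2)
  expect_equal(sum(tm$is_outlier), 100L)
  expect_true(all(tm$tail_moment >= 0))
  expect_identical(simulate_tail_moments(200, 0.2, seed = 9),
                   simulate_tail_moments(200, 0.2, seed = 9))
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_toy_genome(1, 50000, 5, seed = 1))
  invisible(simulate_tail_moments(10, 0.1, seed = 2))
  expect_identical(.Random.seed, before)
})
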