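# random interval set on one short chromosome
rand_set <- function(n, chrom_len, max_w = 300) {
  s <- sample.int(chrom_len - max_w, n, replace = TRUE) - 1L
  data.frame(chrom = "chr1", start = s,
             end = s + sample.int(max_w, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("interval intersection matches the exhaustive pair oracle", {
  a <- data.frame(chrom = "chr1", start = 100, end = 200)
  b <- data.frame(chrom = "chr1", start = 150, end = 250)
  ov <- interval_intersect(a, b)
  expect_equal(nrow(ov), 1L)
  expect_equal(c(ov$start, ov$end), c(150, 200))
  expect_equal(nrow(interval_intersect(
    a, data.frame(chrom = "chr1", start = 300, end = 400))), 0L)
  expect_equal(nrow(interval_intersect(
    a, data.frame(chrom = "chr2", start = 100, end = 200))), 0L)
  # bookended intervals ([0,10) vs [10,20)) do not overlap
  expect_equal(nrow(interval_intersect(
    data.frame(chrom = "chr1", start = 0, end = 10),
    data.frame(chrom = "chr1", start = 10, end = 20))), 0L)
  set.seed(101)
  for (rep in 1:20) {
    a <- rand_set(200, 10000)
    b <- rand_set(200, 10000)
    got <- interval_intersect(a, b)
    want <- oracle_intersect(a, b)
    expect_equal(got, want)
  }
})

test_that("TSS distance classes follow the 5 kb / 500 kb boundaries", {
  tss <- data.frame(chrom = "chr1", pos = 1000000)
  cls <- function(mid) {
    classify_tss_distance(data.frame(chrom = "chr1", start = mid - 10,
                                     end = mid + 10), tss)
  }
  expect_equal(as.character(cls(1003000)$label), "proximal")
  expect_equal(as.character(cls(1005000)$label), "proximal")  # inclusive
  expect_equal(as.character(cls(1005001)$label), "distal")
  expect_equal(as.character(cls(1500000)$label), "distal")    # inclusive
  expect_equal(as.character(cls(1600000)$label), "far")
  expect_equal(cls(1003000)$distance, 3000)
  # peaks on a chromosome without TSS come back far with NA distance
  expect_message(
    out <- classify_tss_distance(data.frame(chrom = "chr9", start = 0,
                                            end = 100), tss),
    "without TSS")
  expect_equal(as.character(out$label), "far")
  expect_true(is.na(out$distance))
})

test_that("TSS classes partition any peak set", {
  set.seed(7)
  g <- make_toy_genome(2, 50000, 15, seed = 7)
  peaks <- do.call(rbind, lapply(1:2, function(i) {
    s <- sample.int(49000, 40) - 1L
    data.frame(chrom = paste0("chr", i), start = s, end = s + 500)
  }))
  cls <- classify_tss_distance(peaks, g$tss)
  expect_equal(sum(table(cls$label)), nrow(peaks))
})

test_that("gene assignment matches the regulatory-domain oracle", {
  # inside the basal domain
  tss <- data.frame(chrom = "chr1", pos = 50000, strand = "+",
                    gene_id = "g1", stringsAsFactors = FALSE)
  hit <- assign_genes(data.frame(chrom = "chr1", start = 47500,
                                 end = 48500), tss)
  expect_equal(hit$gene_id, "g1")
  # beyond max_ext on a single-gene chromosome: unassigned
  far <- assign_genes(data.frame(chrom = "chr1", start = 2049000,
                                 end = 2051000), tss)
  expect_equal(nrow(far), 0L)
  # extension toward a neighbour stops at its basal domain
  tss2 <- data.frame(chrom = "chr1", pos = c(100000, 500000),
                     strand = c("+", "+"),
                     gene_id = c("gA", "gB"), stringsAsFactors = FALSE)
  dom <- gene_regulatory_domains(tss2)
  expect_equal(dom$end[dom$gene_id == "gA"], 495000)   # gB basal start
  expect_equal(dom$start[dom$gene_id == "gB"], 101000) # gA basal end
  # the peak 150 kb from gA lies in both extended domains
  mid_peak <- data.frame(chrom = "chr1", start = 249000, end = 251000)
  got <- assign_genes(mid_peak, tss2)
  expect_true("gA" %in% got$gene_id)
  expect_equal(got, oracle_assign(mid_peak, tss2))
  # randomized agreement with the gene-by-gene oracle
  set.seed(33)
  for (rep in 1:10) {
    n <- 8
    tssr <- data.frame(chrom = "chr1",
                       pos = sort(sample.int(9500, n)) * 100,
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       gene_id = sprintf("g%d", 1:n),
                       stringsAsFactors = FALSE)
    peaks <- rand_set(50, 950000, max_w = 2000)
    got <- assign_genes(peaks, tssr, basal_up = 5000, basal_down = 1000,
                        max_ext = 100000)
    want <- oracle_assign(peaks, tssr, basal_up = 5000, basal_down = 1000,
                          max_ext = 100000)
    got <- got[order(got$peak_idx, got$gene_id), ]
    want <- want[order(want$peak_idx, want$gene_id), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("overlap membership counts match the per-region oracle", {
  A <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                  end = c(50, 150, 400))
  expect_equal(overlap_counts(list(A = A, B = A)),
               c("A_only" = 0L, "A&B" = 3L))
  B <- data.frame(chrom = "chr1", start = 500, end = 600)
  expect_equal(overlap_counts(list(A = A, B = B)),
               c("A_only" = 3L, "A&B" = 0L))
  expect_error(overlap_counts(list(A = A)), "2 or 3")
  expect_error(
    overlap_counts(list(A = data.frame(chrom = "chr1", start = c(0, 10),
                                       end = c(20, 30)), B = B)),
    "internal overlaps")
  set.seed(55)
  for (rep in 1:10) {
    mk <- function() build_universe(rand_set(30, 10000),
                                    data.frame(chrom = character(),
                                               start = integer(),
                                               end = integer()))
    sets <- list(A = mk(), B = mk(), C = mk())
    got <- overlap_counts(sets)
    want <- oracle_overlap_counts(sets)
    expect_equal(sum(got), nrow(sets$A))
    expect_equal(got[sort(names(got))], want[sort(names(want))])
  }
})

test_that("metaprofile bins, drops truncated anchors and is linear", {
  sig <- list(chr1 = rep(1, 1000))
  prof <- metaprofile(sig, data.frame(chrom = "chr1", center = 500),
                      flank = 200, n_bins = 8)
  expect_equal(as.numeric(prof), rep(1, 8))
  # block signal lands in the two central bins
  sig2 <- list(chr1 = c(rep(0, 450), rep(1, 100), rep(0, 450)))
  prof <- metaprofile(sig2, data.frame(chrom = "chr1", center = 500),
                      flank = 200, n_bins = 8)
  expect_equal(as.numeric(prof), c(0, 0, 0, 1, 1, 0, 0, 0))
  expect_equal(attr(prof, "offset"),
               c(-175, -125, -75, -25, 25, 75, 125, 175))
  # linearity and anchor-order invariance
  anchors <- data.frame(chrom = "chr1", center = c(300, 500, 700))
  p1 <- metaprofile(sig2, anchors, flank = 100, n_bins = 4)
  p2 <- metaprofile(lapply(sig2, function(v) 2 * v), anchors,
                    flank = 100, n_bins = 4)
  expect_equal(as.numeric(p2), 2 * as.numeric(p1))
  p3 <- metaprofile(sig2, anchors[c(3, 1, 2), , drop = FALSE],
                    flank = 100, n_bins = 4)
  expect_equal(p1, p3)
  # anchors running off the chromosome are dropped with a message
  expect_message(
    p4 <- metaprofile(sig, data.frame(chrom = "chr1",
                                      center = c(500, 50)),
                      flank = 200, n_bins = 8),
    "truncated")
  expect_equal(as.numeric(p4), rep(1, 8))
  expect_error(metaprofile(sig, data.frame(chrom = character(),
                                           center = numeric()),
                           flank = 200, n_bins = 8), "anchors")
  # oracle: mean over anchors of per-bin means, computed by loops
  set.seed(9)
  sig3 <- list(chr1 = rnorm(2000))
  anch <- data.frame(chrom = "chr1", center = c(400, 900, 1500))
  got <- as.numeric(metaprofile(sig3, anch, flank = 100, n_bins = 10))
  want <- numeric(10)
  for (b in 1:10) {
    vals <- numeric(0)
    for (k in 1:3) {
      w0 <- anch$center[k] - 100 + (b - 1) * 20
      vals <- c(vals, mean(sig3$chr1[(w0 + 1):(w0 + 20)]))
    }
    want[b] <- mean(vals)
  }
  expect_equal(got, want)
})

test_that("fragment coverage counts overlapping fragments per base", {
  cov <- fragment_coverage(data.frame(chrom = "chr1",
                                      start = c(10, 15), end = c(20, 25)),
                           c(chr1 = 30))$chr1
  expect_equal(cov, c(rep(0, 10), rep(1, 5), rep(2, 5), rep(1, 5),
                      rep(0, 5)))
})
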