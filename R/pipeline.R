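#' Run an end-to-end workflow from a configuration list
#'
#' Three workflows tie the stages together, mirroring how the analyses are
#' run from the shell:
#'
#' * `simulate` -- build a toy genome with spiked IP/input libraries and
#'   write every downstream input (chrom.sizes, TSS BED, IP/input SAM and
#'   BED, spike BED plus a sidecar truth TSV).
#' * `chip` -- peak calling ([call_peaks()]) followed by TSS-distance
#'   classification, gene assignment and a signal metaprofile around peak
#'   summits; writes BED6 peaks, a -log10(P) bedGraph, annotation TSVs.
#' * `atac` -- merged region universe ([build_universe()]), per-library
#'   fragment counting, the differential-accessibility rule
#'   ([classify_differential()]) and overlap counts; writes the universe
#'   BED, per-direction differential BEDs and call/overlap TSVs.
#'
#' Every run writes its resolved configuration (`config.json`) and a run
#' log (`log.txt`) next to the outputs; outputs carry no timestamps, so
#' rerunning an identical configuration reproduces byte-identical files.
#'
#' @param config Named list. Common fields: `workflow`
#'   (`"simulate"`/`"chip"`/`"atac"`), `out_dir`, `seed`. Workflow fields
#'   (paths or in-memory objects): `simulate`: `n_chrom`, `chrom_length`,
#'   `n_genes`, `n_spikes`, `spike_width`, `enrichment`, `depth`; `chip`:
#'   `ip`, `input`, `genome`, `tss`, `window`, `ext`, `alpha`, `lam_floor`,
#'   `flank`, `n_bins`; `atac`: `peaks_a`, `peaks_b`, `reads_a`, `reads_b`,
#'   `min_ratio`, `max_p`, `pseudocount`.
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (named paths of everything written). Stage errors propagate with the
#'   stage name prefixed.
#' @examples
#' dir <- tempfile()
#' run_pipeline(list(workflow = "simulate", out_dir = dir, seed = 1,
#'                   chrom_length = 50000, n_genes = 5, n_spikes = 2,
#'                   depth = 20000))
#' @export
run_pipeline <- function(config) {
  if (is.null(config$workflow) ||
      !config$workflow %in% c("simulate", "chip", "atac")) {
    stop("config$workflow must be one of simulate/chip/atac",
         call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required",
                                    call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$workflow,
                simulate = wf_simulate(config),
                chip = wf_chip(config),
                atac = wf_atac(config))
  invisible(res)
}

# stage wrapper: prefix errors with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

default <- function(x, d) if (is.null(x)) d else x

finish_run <- function(config, out_dir, log, artifacts) {
  cfg_path <- file.path(out_dir, "config.json")
  keep <- vapply(config, function(v)
    is.atomic(v) && !is.null(v), logical(1))
  jsonlite::write_json(config[keep], cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  writeLines(log, log_path)
  artifacts$config <- cfg_path
  artifacts$log <- log_path
  list(status = 0L, artifacts = artifacts)
}

# accept an in-memory object or a path for each input kind
resolve_reads <- function(x, chrom_sizes = NULL) {
  if (is.data.frame(x)) x else read_alignments(x, chrom_sizes = chrom_sizes)
}

resolve_genome <- function(x) {
  if (inherits(x, "toy_genome")) return(x$chrom_sizes)
  if (is.character(x) && length(x) == 1L) return(read_chrom_sizes(x))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot interpret genome input", call. = FALSE)
}

resolve_tss <- function(x) {
  if (is.data.frame(x)) return(x)
  bed <- read_bed(x)
  data.frame(chrom = bed$chrom, pos = bed$start,
             strand = if ("strand" %in% names(bed)) bed$strand else "+",
             gene_id = if ("name" %in% names(bed)) bed$name
                       else sprintf("gene%03d", seq_len(nrow(bed))),
             stringsAsFactors = FALSE)
}

resolve_intervals <- function(x) {
  if (is.data.frame(x)) check_intervals(x) else read_bed(x)
}

# non-overlapping random spike regions for the simulate workflow
make_spike_regions <- function(genome, n, width, seed = NULL) {
  with_seed(seed, {
    out <- list()
    for (try in 1:200) {
      cn <- sample(names(genome$chrom_sizes), 1L,
                   prob = genome$chrom_sizes)
      start <- sample.int(genome$chrom_sizes[[cn]] - width, 1L) - 1L
      cand <- data.frame(chrom = cn, start = start, end = start + width,
                         stringsAsFactors = FALSE)
      clash <- any(vapply(out, function(r) {
        r$chrom == cn && r$start < cand$end + width &&
          cand$start < r$end + width   # keep a spike-width gap
      }, logical(1)))
      if (!clash) out[[length(out) + 1L]] <- cand
      if (length(out) == n) break
    }
    if (length(out) < n) stop("could not place ", n,
                              " disjoint spike regions", call. = FALSE)
    sort_intervals(do.call(rbind, out))
  })
}

wf_simulate <- function(config) {
  out_dir <- config$out_dir
  seed <- default(config$seed, 0L)
  n_chrom <- default(config$n_chrom, 1L)
  chrom_length <- default(config$chrom_length, 100000L)
  n_genes <- default(config$n_genes, 20L)
  n_spikes <- default(config$n_spikes, 10L)
  spike_width <- default(config$spike_width, 500L)
  enrichment <- default(config$enrichment, 20)
  depth <- default(config$depth, 2e5)
  log <- character()
  genome <- stage("genome", make_toy_genome(n_chrom, chrom_length, n_genes,
                                            seed = seed))
  spikes <- stage("spikes",
                  make_spike_regions(genome, n_spikes, spike_width,
                                     seed = seed + 1L))
  design <- spike_design(genome, spikes, enrichment = enrichment,
                         depth = depth)
  ip <- stage("ip", simulate_chip_library(genome, design, seed = seed + 2L))
  input <- stage("input", simulate_chip_library(genome, design,
                                                is_input = TRUE,
                                                seed = seed + 3L))
  log <- c(log, sprintf("genome: %d chrom x %d bp, %d TSS", n_chrom,
                        chrom_length, n_genes),
           sprintf("spikes: %d x %d bp, enrichment %g", n_spikes,
                   spike_width, enrichment),
           sprintf("libraries: IP %d reads, input %d reads", nrow(ip),
                   nrow(input)))
  a <- list()
  a$chrom_sizes <- write_chrom_sizes(genome$chrom_sizes,
                                     file.path(out_dir, "genome.chrom.sizes"))
  a$tss <- write_bed(data.frame(chrom = genome$tss$chrom,
                                start = genome$tss$pos,
                                end = genome$tss$pos + 1L),
                     file.path(out_dir, "tss.bed"),
                     name = genome$tss$gene_id,
                     score = rep(0L, nrow(genome$tss)),
                     strand = genome$tss$strand)
  a$spikes <- write_bed(spikes, file.path(out_dir, "spikes.bed"))
  truth <- cbind(spikes, data.frame(enrichment = design$enrichment))
  a$spike_truth <- write_tsv(truth, file.path(out_dir, "spikes_truth.tsv"))
  a$ip_sam <- write_sam(ip, genome$chrom_sizes, file.path(out_dir, "ip.sam"))
  a$input_sam <- write_sam(input, genome$chrom_sizes,
                           file.path(out_dir, "input.sam"))
  a$ip_bed <- write_alignments_bed(ip, file.path(out_dir, "ip.bed"))
  a$input_bed <- write_alignments_bed(input,
                                      file.path(out_dir, "input.bed"))
  finish_run(config, out_dir, log, a)
}

wf_chip <- function(config) {
  out_dir <- config$out_dir
  chrom_sizes <- stage("genome", resolve_genome(config$genome))
  ip <- stage("read ip", resolve_reads(config$ip, chrom_sizes))
  input <- stage("read input", resolve_reads(config$input, chrom_sizes))
  window <- default(config$window, 50L)
  ext <- default(config$ext, 150L)
  alpha <- default(config$alpha, 1e-3)
  lam_floor <- default(config$lam_floor, "auto")
  flank <- default(config$flank, 2000L)
  n_bins <- default(config$n_bins, 100L)
  pc <- stage("callpeaks",
              call_peaks(ip, input, chrom_sizes, window = window,
                         ext = ext, alpha = alpha, lam_floor = lam_floor))
  log <- c(sprintf("IP: %d reads after dedup; input: %d",
                   pc$totals[["ip"]], pc$totals[["input"]]),
           sprintf("window %d bp, ext %d bp, alpha %g, lambda floor %.6g",
                   window, ext, alpha, pc$lam_floor),
           sprintf("%d peak(s) called", nrow(pc$peaks)))
  a <- list()
  b6 <- peaks_to_bed6(pc$peaks)
  a$peaks <- write_bed(b6[c("chrom", "start", "end")],
                       file.path(out_dir, "peaks.bed"),
                       name = b6$name, score = b6$score,
                       strand = b6$strand)
  s <- pc$window_stats
  a$bedgraph <- write_bedgraph(
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               value = round(-log10(pmax(s$pval, 1e-300)), 4L)),
    file.path(out_dir, "windows_neglog10p.bedgraph"))
  a$window_stats <- write_tsv(s, file.path(out_dir, "window_stats.tsv"))
  if (!is.null(config$tss) && nrow(pc$peaks)) {
    tss <- stage("tss", resolve_tss(config$tss))
    cls <- stage("classify_tss_distance",
                 classify_tss_distance(pc$peaks, tss))
    a$tss_classes <- write_tsv(
      cbind(pc$peaks[c("chrom", "start", "end")],
            data.frame(label = as.character(cls$label),
                       distance = cls$distance)),
      file.path(out_dir, "tss_classes.tsv"))
    genes <- stage("assign_genes",
                   assign_genes(pc$peaks, tss, chrom_sizes = chrom_sizes))
    a$gene_assignments <- write_tsv(genes,
                                    file.path(out_dir,
                                              "gene_assignments.tsv"))
    log <- c(log, sprintf("TSS classes: %s",
                          paste(sprintf("%s=%d", levels(cls$label),
                                        table(cls$label)),
                                collapse = " ")))
  }
  if (nrow(pc$peaks)) {
    frags <- extend_reads(if (pc$params$dedup) dedupe_reads(ip) else ip,
                          chrom_sizes, ext)
    cov <- fragment_coverage(frags, chrom_sizes)
    prof <- stage("metaprofile",
                  metaprofile(cov, data.frame(chrom = pc$peaks$chrom,
                                              center = pc$peaks$summit),
                              flank = flank, n_bins = n_bins))
    a$metaprofile <- write_tsv(
      data.frame(bin_center_offset = attr(prof, "offset"),
                 mean_signal = round(as.numeric(prof), 6L)),
      file.path(out_dir, "metaprofile.tsv"))
  } else {
    log <- c(log, "no peaks: metaprofile skipped")
  }
  finish_run(config, out_dir, log, a)
}

wf_atac <- function(config) {
  out_dir <- config$out_dir
  peaks_a <- stage("peaks_a", resolve_intervals(config$peaks_a))
  peaks_b <- stage("peaks_b", resolve_intervals(config$peaks_b))
  min_ratio <- default(config$min_ratio, 4)
  max_p <- default(config$max_p, 0.01)
  pseudocount <- default(config$pseudocount, 1)
  universe <- stage("build_universe", build_universe(peaks_a, peaks_b))
  reads_a <- lapply(config$reads_a, resolve_reads)
  reads_b <- lapply(config$reads_b, resolve_reads)
  frag_of <- function(r) data.frame(chrom = r$chrom, start = r$pos,
                                    end = r$pos + r$length,
                                    stringsAsFactors = FALSE)
  frags <- c(lapply(reads_a, frag_of), lapply(reads_b, frag_of))
  names(frags) <- c(paste0("A", seq_along(reads_a)),
                    paste0("B", seq_along(reads_b)))
  rc <- stage("count_fragments",
              count_fragments(universe, frags,
                              condition = rep(c("A", "B"),
                                              c(length(reads_a),
                                                length(reads_b)))))
  dc <- stage("classify_differential",
              classify_differential(rc, min_ratio = min_ratio,
                                    max_p = max_p,
                                    pseudocount = pseudocount))
  ov <- stage("overlap_counts",
              overlap_counts(list(A = build_universe(peaks_a,
                                                     peaks_a[0, ]),
                                  B = build_universe(peaks_b,
                                                     peaks_b[0, ]))))
  log <- c(sprintf("universe: %d regions from %d + %d peaks",
                   nrow(universe), nrow(peaks_a), nrow(peaks_b)),
           sprintf("libraries: %s",
                   paste(sprintf("%s=%d", names(frags),
                                 vapply(frags, nrow, integer(1))),
                         collapse = " ")),
           sprintf("thresholds: ratio >= %g, P <= %g, pseudocount %g",
                   min_ratio, max_p, pseudocount),
           sprintf("%d differential region(s)", sum(dc$differential)))
  a <- list()
  a$universe <- write_bed(universe, file.path(out_dir, "universe.bed"))
  a$calls <- write_tsv(as.data.frame(dc),
                       file.path(out_dir, "diff_calls.tsv"))
  for (d in attr(dc, "params")$conditions) {
    sel <- dc$direction == d
    a[[paste0("diff_", d)]] <- write_bed(
      as.data.frame(dc)[sel, c("chrom", "start", "end")],
      file.path(out_dir, sprintf("differential_%s.bed", d)))
  }
  a$overlaps <- write_tsv(data.frame(category = names(ov),
                                     count = as.integer(ov)),
                          file.path(out_dir, "overlap_counts.tsv"))
  finish_run(config, out_dir, log, a)
}
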