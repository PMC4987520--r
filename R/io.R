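#' Read aligned reads from SAM/BAM or BED
#'
#' SAM/BAM parsing goes through Rsamtools; unmapped records are dropped
#' with a message and 1-based SAM positions are converted to the package's
#' 0-based half-open convention. BED input is taken as 3- or 6-column
#' alignment records (`chrom start end [name score strand]`); missing
#' strand defaults to `+` and the read length is `end - start`.
#'
#' @param path Input file.
#' @param format `"auto"` (default, by extension), `"bed"`, `"sam"` or
#'   `"bam"`.
#' @param chrom_sizes Optional named vector; reads on chromosomes absent
#'   from it raise an error listing the offenders.
#' @return Aligned-read data.frame (`chrom`, `pos`, `strand`, `length`).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t150\tr1\t0\t+", f)
#' read_alignments(f)
#' @export
read_alignments <- function(path, format = c("auto", "bed", "sam", "bam"),
                            chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path,
                               call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  reads <- if (format == "bed") read_alignments_bed(path)
           else read_alignments_sam(path, is_bam = format == "bam")
  zero <- reads$length <= 0
  if (any(zero)) {
    message(sum(zero), " zero-length record(s) dropped")
    reads <- reads[!zero, , drop = FALSE]
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop("read(s) on chromosome(s) not in chrom.sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  rownames(reads) <- NULL
  reads
}

read_alignments_bed <- function(path) {
  x <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, fill = FALSE,
                      comment.char = ""),
    error = function(e) {
      stop("malformed BED in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (ncol(x) < 3L) stop("BED file needs >= 3 columns: ", path,
                         call. = FALSE)
  x[[2]] <- suppressWarnings(as.integer(x[[2]]))
  x[[3]] <- suppressWarnings(as.integer(x[[3]]))
  bad <- which(is.na(x[[2]]) | is.na(x[[3]]) | x[[2]] < 0 |
                 x[[3]] < x[[2]])
  if (length(bad)) {
    stop("malformed BED record at line ", bad[1L], " of ", path,
         call. = FALSE)
  }
  strand <- if (ncol(x) >= 6L) x[[6]] else rep("+", nrow(x))
  strand[!(strand %in% c("+", "-"))] <- "+"
  data.frame(chrom = x[[1]], pos = x[[2]], strand = strand,
             length = x[[3]] - x[[2]], stringsAsFactors = FALSE)
}

read_alignments_sam <- function(path, is_bam = FALSE) {
  bam <- if (is_bam) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "qwidth",
                                        "flag"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  unmapped <- bitwAnd(x$flag, 4L) != 0L | is.na(x$pos)
  if (any(unmapped)) message(sum(unmapped), " unmapped record(s) dropped")
  keep <- !unmapped
  data.frame(chrom = as.character(x$rname[keep]),
             pos = x$pos[keep] - 1L,
             strand = as.character(x$strand[keep]),
             length = x$qwidth[keep], stringsAsFactors = FALSE)
}

#' Write aligned reads as minimal SAM
#'
#' Emits a minimal mapped-only SAM: `@HD`/`@SQ` header then one record per
#' read with flag 0/16, 1-based POS, CIGAR `<length>M` and `*` sequence.
#'
#' @param reads Aligned-read data.frame.
#' @param chrom_sizes Named vector of chromosome lengths (for `@SQ` lines).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_sizes, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  recs <- if (nrow(reads)) {
    sprintf("r%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
            seq_len(nrow(reads)),
            ifelse(reads$strand == "-", 16L, 0L),
            reads$chrom, reads$pos + 1L, reads$length)
  } else character()
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Write aligned reads as 6-column BED
#'
#' @param reads Aligned-read data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(reads, path) {
  write_bed(data.frame(chrom = reads$chrom, start = reads$pos,
                       end = reads$pos + reads$length,
                       stringsAsFactors = FALSE),
            path,
            name = if (nrow(reads)) sprintf("r%d", seq_len(nrow(reads)))
                   else character(),
            score = rep(0L, nrow(reads)), strand = reads$strand)
}

#' Read and write BED interval files
#'
#' Plain tab-separated BED, 0-based half-open, 3 or 6 columns, no header.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`).
#' @param path File path.
#' @param name,score,strand Optional per-interval BED6 columns; all three
#'   must be given together.
#' @return `write_bed`: `path` invisibly. `read_bed`: interval data.frame
#'   (with `name`, `score`, `strand` when present in the file).
#' @export
write_bed <- function(intervals, path, name = NULL, score = NULL,
                      strand = NULL) {
  intervals <- check_intervals(intervals, "intervals")
  df <- intervals[c("chrom", "start", "end")]
  six <- !is.null(name) || !is.null(score) || !is.null(strand)
  if (six) {
    if (is.null(name) || is.null(score) || is.null(strand)) {
      stop("BED6 output needs name, score and strand together",
           call. = FALSE)
    }
    df$name <- name
    df$score <- score
    df$strand <- strand
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "")
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 6L) names(x)[4:6] <- c("name", "score", "strand")
  check_intervals(x, path)
}

#' Convert called peaks to BED6 columns
#'
#' Peaks are named by rank (1 = smallest peak P-value) and scored as
#' `floor(min(1000, -10 * log10(min_pval)))`.
#'
#' @param peaks Peak data.frame from [call_peaks()]/[merge_peaks()].
#' @return data.frame with BED6 columns.
#' @export
peaks_to_bed6 <- function(peaks) {
  rank <- rank(peaks$min_pval, ties.method = "first")
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             name = sprintf("peak_%d", rank),
             score = as.integer(floor(pmin(
               1000, -10 * log10(pmax(peaks$min_pval, 1e-300))))),
             strand = ".", stringsAsFactors = FALSE)
}

#' Write a bedGraph track
#'
#' Four-column bedGraph; intervals must be sorted and non-overlapping
#' within each chromosome.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  track <- check_intervals(track, "track")
  for (cn in unique(track$chrom)) {
    i <- which(track$chrom == cn)
    if (length(i) > 1L &&
        (is.unsorted(track$start[i]) ||
           any(track$start[i][-1] < track$end[i][-length(i)]))) {
      stop("bedGraph intervals must be sorted and non-overlapping",
           call. = FALSE)
    }
  }
  utils::write.table(track[c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write plain TSV tables
#'
#' Header-row TSV with no quoting dialect: writing a field that itself
#' contains a tab is refused.
#'
#' @param table data.frame to write.
#' @param path File path.
#' @return `write_tsv`: `path` invisibly. `read_tsv`: data.frame.
#' @export
write_tsv <- function(table, path) {
  chr_cols <- vapply(table, is.character, logical(1))
  if (any(vapply(table[chr_cols], function(v) any(grepl("\t", v)),
                 logical(1)))) {
    stop("field contains a tab character; TSV output has no quoting",
         call. = FALSE)
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}
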