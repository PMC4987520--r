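#' Construct a toy genome with annotated TSSs
#'
#' A toy genome is the coordinate system every other stage runs on: a set of
#' named chromosomes with lengths, plus a table of transcription start sites
#' (TSSs) standing in for a gene annotation. It exists so that peak calling,
#' annotation and differential accessibility can be exercised end to end on
#' data with known ground truth.
#'
#' @param n_chrom Number of chromosomes (>= 1), named `chr1`, `chr2`, ...
#' @param chrom_length Length of every chromosome in bp (>= 10000).
#' @param n_genes Total number of TSSs to place, uniformly at random across
#'   chromosomes without duplicated positions on a chromosome. May be 0.
#' @param seed Integer seed; the same seed always yields the identical genome.
#' @return An object of class `toy_genome`: a list with `chrom_sizes` (named
#'   integer vector) and `tss` (data.frame with columns `chrom`, `pos`
#'   (0-based bp), `strand`, `gene_id`).
#' @examples
#' g <- make_toy_genome(2, 50000, 10, seed = 3)
#' g$chrom_sizes
#' head(g$tss)
#' @export
make_toy_genome <- function(n_chrom, chrom_length, n_genes, seed = NULL) {
  check_count(n_chrom, "n_chrom", min = 1L)
  check_count(chrom_length, "chrom_length", min = 10000L)
  check_count(n_genes, "n_genes", min = 0L)
  chrom_sizes <- rep(as.integer(chrom_length), n_chrom)
  names(chrom_sizes) <- paste0("chr", seq_len(n_chrom))
  tss <- with_seed(seed, {
    if (n_genes == 0L) {
      data.frame(chrom = character(), pos = integer(),
                 strand = character(), gene_id = character(),
                 stringsAsFactors = FALSE)
    } else {
      chrom <- sample(names(chrom_sizes), n_genes, replace = TRUE)
      pos <- integer(n_genes)
      for (cn in unique(chrom)) {
        idx <- which(chrom == cn)
        pos[idx] <- sample.int(chrom_sizes[[cn]], length(idx)) - 1L
      }
      data.frame(chrom = chrom, pos = pos,
                 strand = sample(c("+", "-"), n_genes, replace = TRUE),
                 gene_id = sprintf("gene%03d", seq_len(n_genes)),
                 stringsAsFactors = FALSE)
    }
  })
  tss <- tss[order(tss$chrom, tss$pos), , drop = FALSE]
  rownames(tss) <- NULL
  structure(list(chrom_sizes = chrom_sizes, tss = tss),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosome(s), %s bp total, %d TSS\n",
              length(x$chrom_sizes),
              format(sum(as.numeric(x$chrom_sizes)), big.mark = ","),
              nrow(x$tss)))
  invisible(x)
}

#' Read and write chrom.sizes files
#'
#' Plain two-column text (`chrom<TAB>length`), the UCSC chrom.sizes format.
#'
#' @param path File path.
#' @return `read_chrom_sizes`: a named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "integer"))
  if (anyDuplicated(x$chrom)) stop("duplicated chromosome names in ", path)
  if (any(x$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(x$length, x$chrom)
}

#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(chrom = names(chrom_sizes), length = as.integer(chrom_sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
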