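#' Ig rearrangement frequency from qPCR cycle thresholds
#'
#' The 2^deltaCt quantification: with deltaCt = Ct_Actb - Ct_Ig, the
#' rearrangement frequency is 2^deltaCt. A target amplifying one cycle later
#' than the Actb reference is half as abundant.
#'
#' @param ct_actb Actb reference cycle threshold(s), cycles.
#' @param ct_ig Ig target cycle threshold(s), cycles.
#' @return Frequency 2^(ct_actb - ct_ig), vectorized.
#' @examples
#' rearrangement_frequency(20, 22)  # 0.25
#' @export
rearrangement_frequency <- function(ct_actb, ct_ig) {
  if (any(!is.finite(ct_actb))) {
    stop("missing or non-finite Actb reference Ct", call. = FALSE)
  }
  if (any(!is.finite(ct_ig))) {
    stop("missing or non-finite Ig Ct", call. = FALSE)
  }
  2^(ct_actb - ct_ig)
}

#' Relative expression from qPCR cycle thresholds
#'
#' The deltaCt method with Actb as the reference gene: expression relative
#' to the reference is 2^(ct_actb - ct_gene). Combine with
#' [normalize_to_control()] for fold-of-control (deltadeltaCt) values.
#'
#' @param ct_gene Target-gene cycle threshold(s), cycles.
#' @param ct_actb Actb reference cycle threshold(s), cycles.
#' @return Relative expression, vectorized.
#' @examples
#' relative_expression(25, 20)  # 2^-5
#' @export
relative_expression <- function(ct_gene, ct_actb) {
  if (any(!is.finite(ct_actb))) {
    stop("missing or non-finite Actb reference Ct", call. = FALSE)
  }
  if (any(!is.finite(ct_gene))) {
    stop("missing or non-finite gene Ct", call. = FALSE)
  }
  2^(ct_actb - ct_gene)
}

#' Normalize per-sample values to the control-group mean
#'
#' Divides every value by the mean of the control-group values, so the
#' control mean maps to exactly 1.
#'
#' @param values Numeric vector of per-sample values.
#' @param group Character/factor vector of group labels, same length.
#' @param control Label of the control group (default `"control"`).
#' @return Numeric vector of fold-of-control values.
#' @examples
#' normalize_to_control(c(0.2, 0.3, 0.125),
#'                      c("control", "control", "mutant"))
#' @export
normalize_to_control <- function(values, group, control = "control") {
  if (length(values) != length(group)) {
    stop("'values' and 'group' must have equal length", call. = FALSE)
  }
  ctrl <- values[group == control]
  if (!length(ctrl)) stop("no sample in group '", control, "'",
                          call. = FALSE)
  m <- mean(ctrl)
  if (!is.finite(m) || m == 0) {
    stop("control-group mean is zero or non-finite", call. = FALSE)
  }
  values / m
}

#' Classify comet-assay outlier cells by median absolute deviation
#'
#' A cell is an outlier when the absolute deviation of its tail moment from
#' the sample median is at least 3 median absolute deviations (MAD,
#' unscaled: the median of the absolute deviations, with no consistency
#' factor). When the MAD is zero -- at least half the cells share the
#' median value -- the literal rule would flag every cell, so instead only
#' cells with any nonzero deviation are flagged, preserving the rule's
#' intent of marking departures from a tight distribution.
#'
#' @param tail_moments Numeric vector of per-cell tail moments (>= 3
#'   cells).
#' @param k Number of MADs defining an outlier (default 3, inclusive).
#' @return List with `outlier` (logical per cell), `median`, `mad`,
#'   `n_outliers` and `outlier_fraction`.
#' @examples
#' mad_outlier_classify(c(2, 3, 3, 4, 20))$outlier  # F F F F T
#' @export
mad_outlier_classify <- function(tail_moments, k = 3) {
  if (length(tail_moments) < 3L) {
    stop("need at least 3 cells to classify outliers", call. = FALSE)
  }
  if (any(!is.finite(tail_moments))) {
    stop("tail moments must be finite", call. = FALSE)
  }
  m <- stats::median(tail_moments)
  dev <- abs(tail_moments - m)
  mad <- stats::median(dev)
  outlier <- if (mad > 0) dev >= k * mad else dev > 0
  list(outlier = outlier, median = m, mad = mad,
       n_outliers = sum(outlier), outlier_fraction = mean(outlier))
}

#' Score gammaH2AX foci counts as positive or negative cells
#'
#' A cell is positive when it shows at least `threshold` foci (default 4;
#' 0-3 foci is negative). Per-sample positive fractions are reported both
#' over all cells and over scored cells only (cells with `NA` counts are
#' unscorable); with complete data the two coincide. Samples with fewer
#' than `min_cells` scored cells are flagged with a warning.
#'
#' @param records data.frame with columns `sample_id` and `n_foci`
#'   (non-negative integer counts; `NA` marks an unscorable cell).
#' @param threshold Minimum focus count for a positive cell (default 4).
#' @param min_cells Cells per sample below which a warning is issued
#'   (default 50).
#' @return List with `positive` (logical per cell) and `per_sample`, a
#'   data.frame of `sample_id`, `n_cells`, `n_scored`, `n_positive`,
#'   `frac_positive_raw` (denominator: all cells) and `frac_positive`
#'   (denominator: scored cells).
#' @examples
#' foci_classify(data.frame(sample_id = "m1", n_foci = c(0, 3, 4, 7)),
#'               min_cells = 1)
#' @export
foci_classify <- function(records, threshold = 4L, min_cells = 50L) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "n_foci") %in% names(records)))
  n <- records$n_foci
  if (any(n < 0 | n != floor(n), na.rm = TRUE)) {
    stop("'n_foci' must be non-negative integers", call. = FALSE)
  }
  positive <- n >= threshold
  per_sample <- do.call(rbind, lapply(split(seq_len(nrow(records)),
                                            records$sample_id),
                                      function(i) {
    scored <- !is.na(n[i])
    data.frame(sample_id = records$sample_id[i[1L]],
               n_cells = length(i), n_scored = sum(scored),
               n_positive = sum(positive[i], na.rm = TRUE),
               frac_positive_raw = sum(positive[i], na.rm = TRUE) /
                 length(i),
               frac_positive = if (any(scored))
                 mean(positive[i][scored]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  low <- per_sample$n_scored < min_cells
  if (any(low)) {
    warning("sample(s) with fewer than ", min_cells, " scored cells: ",
            paste(per_sample$sample_id[low], collapse = ", "),
            call. = FALSE)
  }
  list(positive = positive, per_sample = per_sample)
}

#' Absolute lineage cell count from CBC and flow cytometry
#'
#' Multiplies the white-blood-cell count from a complete blood count by the
#' lineage-specific fraction from flow cytometry, giving the absolute
#' number of cells of that lineage per unit volume.
#'
#' @param wbc WBC count (cells per microlitre).
#' @param lineage_fraction Lineage fraction in [0, 1].
#' @return Cells per microlitre, vectorized.
#' @examples
#' lineage_cell_count(5000, 0.30)  # 1500
#' @export
lineage_cell_count <- function(wbc, lineage_fraction) {
  if (any(!is.finite(wbc) | wbc < 0)) {
    stop("'wbc' must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(lineage_fraction) | lineage_fraction < 0 |
            lineage_fraction > 1)) {
    stop("'lineage_fraction' must lie in [0, 1]", call. = FALSE)
  }
  wbc * lineage_fraction
}

#' Group summary of per-sample values
#'
#' Mean with standard deviation (and standard error) per group, the usual
#' figure-panel summary across mice.
#'
#' @param values Numeric vector.
#' @param group Group labels, same length.
#' @return data.frame with `group`, `n`, `mean`, `sd`, `sem`.
#' @export
group_summary <- function(values, group) {
  if (length(values) != length(group)) {
    stop("'values' and 'group' must have equal length", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(values, group), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  out <- cbind(data.frame(group = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
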