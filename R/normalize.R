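#' Log2-transform a linear-scale intensity matrix
#'
#' Entries are floored at `floor` before taking log2, so non-positive or
#' near-zero intensities map to `log2(floor)` rather than -Inf.
#'
#' @param raw numeric matrix of linear-scale intensities (probes x samples).
#' @param floor positive linear value at which intensities are clipped.
#' @return matrix of log2 intensities with the same dimnames.
#' @export
log2_transform <- function(raw, floor = 1) {
  if (!is.matrix(raw) || !is.numeric(raw)) stop("raw must be a numeric matrix")
  if (!is.finite(floor) || floor <= 0) stop("floor must be a positive number")
  bad <- which(!is.finite(raw), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("ingestion error: non-finite intensity at probe '",
         rownames(raw)[bad[1, 1]] %||% bad[1, 1], "', sample '",
         colnames(raw)[bad[1, 2]] %||% bad[1, 2], "'")
  }
  log2(pmax(raw, floor))
}

#' Per-chip percentile-shift normalization
#'
#' From every entry of each sample column, the column's `percentile`-th
#' percentile is subtracted, so that afterwards that percentile equals zero
#' in every column. The percentile uses linear interpolation between closest
#' ranks (`r = 1 + q(n-1)`, R's default quantile type 7). This removes any
#' additive per-column (per-array) offset exactly and preserves within-column
#' ordering.
#'
#' @param mat log2 intensity matrix (probes x samples).
#' @param percentile percentile in (0, 100); default 75.
#' @return normalized matrix, with the per-sample shifts applied stored in
#'   `attr(, "shifts")`.
#' @export
percentile_shift <- function(mat, percentile = 75) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  if (nrow(mat) < 2L) stop("each sample column needs >= 2 values")
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  shifts <- apply(mat, 2L, quantile, probs = percentile / 100,
                  names = FALSE, type = 7)
  out <- sweep(mat, 2L, shifts)
  attr(out, "shifts") <- shifts
  out
}

#' Baseline transformation to the median of all samples
#'
#' Subtracts from every probe row its median across all samples, so every
#' output row has median zero. The median is taken over all samples (both
#' organs, genotypes and conditions). Idempotent, and removes any additive
#' per-row offset exactly.
#'
#' @param mat normalized log2 matrix (probes x samples).
#' @return baselined matrix.
#' @export
baseline_to_median <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  out <- sweep(mat, 1L, apply(mat, 1L, median))
  attr(out, "shifts") <- NULL
  out
}

#' Normalize a raw intensity matrix
#'
#' Convenience chain: probes with any missing or non-finite intensity are
#' dropped, then [log2_transform()], [percentile_shift()] and
#' [baseline_to_median()] are applied in that order.
#'
#' @inheritParams log2_transform
#' @inheritParams percentile_shift
#' @return baselined log2 matrix; dropped probes are recorded in
#'   `attr(, "dropped_probes")`.
#' @export
normalize_expression <- function(raw, floor = 1, percentile = 75) {
  keep <- apply(is.finite(raw), 1L, all)
  dropped <- rownames(raw)[!keep]
  mat <- log2_transform(raw[keep, , drop = FALSE], floor = floor)
  mat <- baseline_to_median(percentile_shift(mat, percentile = percentile))
  attr(mat, "dropped_probes") <- dropped
  mat
}
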