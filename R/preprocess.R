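# Log transformation and quantile normalization, including alignment of
# external cohorts to a frozen reference distribution so that a model trained
# on one cohort can be applied to new samples (even one at a time) without
# retraining.

#' Log2-transform an expression matrix
#'
#' @param mat an [expression_matrix()].
#' @param offset additive offset applied before taking log2 (e.g. 1 to keep
#'   zero intensities finite). All `value + offset` must be > 0.
#' @return An [expression_matrix()] with values `log2(value + offset)`.
#' @export
log2_transform <- function(mat, offset = 0) {
  v <- mat$values + offset
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive value after offset at row %d ('%s'), column %d ('%s')",
                 bad[1L], mat$probe_ids[bad[1L]], bad[2L], mat$sample_ids[bad[2L]]))
  }
  expression_matrix(log2(v), mat$probe_ids, mat$gene_symbols, mat$sample_ids)
}

# Replace one column's values by reference values at the column's within-
# column ranks; a tied block receives the mean of the reference values over
# the tied positions (the standard quantile-normalization tie convention).
align_column <- function(col, ref) {
  r <- rank(col, ties.method = "average")
  k <- ave(col, match(col, col), FUN = length)   # tie-block multiplicity
  lo <- as.integer(round(r - (k - 1) / 2))
  hi <- as.integer(round(r + (k - 1) / 2))
  cs <- cumsum(ref)
  below <- cs[pmax(lo - 1L, 1L)]
  below[lo == 1L] <- 0
  (cs[hi] - below) / k
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's empirical distribution onto the across-sample mean
#' of the sorted columns: after normalization each column's sorted values
#' equal that common reference and within-column rank order is preserved.
#' With a single sample the matrix is returned unchanged.
#'
#' @param mat an [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat$values) < 2L) return(mat)
  ref <- rowMeans(apply(mat$values, 2L, sort))
  out <- apply(mat$values, 2L, align_column, ref = ref)
  expression_matrix(out, mat$probe_ids, mat$gene_symbols, mat$sample_ids)
}

#' Extract the frozen reference distribution of a cohort
#'
#' The reference is the per-rank mean of the column-sorted values — the
#' distribution onto which external samples are later mapped when a trained
#' model is applied without retraining.
#'
#' @param mat an [expression_matrix()] (typically already normalized).
#' @return A list with class `reference_quantiles`: `values` (sorted,
#'   length = transcript count) and `n_source_samples`.
#' @export
reference_quantiles <- function(mat) {
  vals <- unname(rowMeans(apply(mat$values, 2L, sort)))
  structure(list(values = vals, n_source_samples = ncol(mat$values)),
            class = "reference_quantiles")
}

#' Align a cohort to a frozen reference distribution
#'
#' Per-sample rank replacement: each column's value at within-column rank r
#' becomes the r-th reference quantile (ties receive the mean of the tied
#' reference positions). Each sample is mapped independently, so the
#' operation works identically for a whole cohort or a single new patient.
#'
#' @param mat an [expression_matrix()].
#' @param reference a [reference_quantiles()] object (or bare numeric vector)
#'   of length equal to the transcript count.
#' @return An [expression_matrix()] whose tie-free columns, sorted, equal the
#'   reference exactly.
#' @export
align_to_reference <- function(mat, reference) {
  ref <- if (inherits(reference, "reference_quantiles")) reference$values
         else as.numeric(reference)
  if (length(ref) != nrow(mat$values))
    stop(sprintf("reference length (%d) does not match transcript count (%d)",
                 length(ref), nrow(mat$values)))
  if (is.unsorted(ref)) stop("reference quantiles must be non-decreasing")
  out <- apply(mat$values, 2L, align_column, ref = ref)
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(mat$values))
  expression_matrix(out, mat$probe_ids, mat$gene_symbols, mat$sample_ids)
}
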