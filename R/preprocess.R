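#' Filter genes by dynamic range across conditions
#'
#' Keeps a gene if, in at least one condition, its maximum expression exceeds
#' `floor` and also exceeds `fold` times its minimum expression. This is the
#' standard "changes at all, and is expressed at all" filter for FPKM-like
#' time courses; the `max > fold * min` form is well defined when the minimum
#' is zero, so no pseudocount is used.
#'
#' @param matrices list of [expression_matrix()] objects over the same gene
#'   universe (one per condition), raw-scale nonnegative values.
#' @param fold fold-change threshold (default 2).
#' @param floor minimum required maximum expression (default 5, FPKM-scale).
#' @return character vector of kept gene ids (in the matrices' row order).
#' @export
filter_dynamic_genes <- function(matrices, fold = 2, floor = 5) {
  if (is_expression_matrix(matrices)) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1, all(vapply(matrices, is_expression_matrix, TRUE)))
  genes <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), genes))
      stop("matrices do not share the same gene universe")
  }
  keep <- rep(FALSE, length(genes))
  for (m in matrices) {
    mx <- apply(m, 1, max)
    mn <- apply(m, 1, min)
    keep <- keep | (mx > floor & mx > fold * mn)
  }
  genes[keep]
}

#' Z-normalize each gene's expression profile
#'
#' Centers and scales every row to mean 0 and standard deviation 1
#' (sample standard deviation, denominator T-1). Rows with zero variance must
#' be removed first ([drop_zero_variance()]); their presence is an error
#' listing the offending genes.
#'
#' @param matrix an [expression_matrix()].
#' @return an [expression_matrix()] with stage `"zscore"`.
#' @export
znormalize <- function(matrix) {
  stopifnot(is_expression_matrix(matrix))
  sds <- apply(matrix, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance genes (remove before z-normalization): ",
         paste(rownames(matrix)[sds == 0], collapse = ", "))
  z <- (matrix - rowMeans(matrix)) / sds
  expression_matrix(unclass(z), condition = attr(matrix, "condition"),
                    stage = "zscore")
}

#' Drop zero-variance genes, with a warning
#'
#' @param matrix an [expression_matrix()].
#' @return the matrix without constant rows; warns with the number removed.
#' @export
drop_zero_variance <- function(matrix) {
  stopifnot(is_expression_matrix(matrix))
  sds <- apply(matrix, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) removed before z-normalization")
    matrix <- expression_matrix(unclass(matrix)[sds > 0, , drop = FALSE],
                                condition = attr(matrix, "condition"),
                                stage = attr(matrix, "stage"))
  }
  matrix
}

#' Upper-quartile normalization of raw counts
#'
#' Divides each sample's counts by the 75th percentile of that sample's
#' non-zero counts (linear interpolation between order statistics at position
#' `0.75 * (n - 1)`, i.e. R's default quantile type 7). Zeros stay zero.
#'
#' @param matrix an [expression_matrix()] of nonnegative counts; every sample
#'   must have at least 4 non-zero genes.
#' @return an [expression_matrix()] with stage `"normalized"`.
#' @export
normalize_counts_q75 <- function(matrix) {
  stopifnot(is_expression_matrix(matrix))
  if (any(matrix < 0)) stop("counts must be nonnegative")
  out <- unclass(matrix)
  for (j in seq_len(ncol(out))) {
    nz <- out[, j][out[, j] > 0]
    if (length(nz) == 0)
      stop("sample '", colnames(out)[j], "' has all-zero counts")
    if (length(nz) < 4)
      stop("sample '", colnames(out)[j], "' has fewer than 4 non-zero genes")
    out[, j] <- out[, j] / stats::quantile(nz, 0.75, names = FALSE, type = 7)
  }
  expression_matrix(out, condition = attr(matrix, "condition"),
                    stage = "normalized")
}

#' Filter genes by a minimum count in every sample
#'
#' @param matrix an [expression_matrix()] of raw counts.
#' @param min_count minimum per-sample count required (default 1).
#' @return character vector of kept gene ids.
#' @export
filter_min_reads <- function(matrix, min_count = 1) {
  stopifnot(is_expression_matrix(matrix))
  rownames(matrix)[apply(unclass(matrix) >= min_count, 1, all)]
}

#' Subset an expression matrix to a gene set, preserving attributes
#'
#' @param matrix an [expression_matrix()].
#' @param genes gene ids to keep (order of the matrix is preserved).
#' @return an [expression_matrix()].
#' @export
subset_genes <- function(matrix, genes) {
  stopifnot(is_expression_matrix(matrix))
  keep <- rownames(matrix)[rownames(matrix) %in% genes]
  if (!length(keep)) stop("no requested genes present in the matrix")
  expression_matrix(unclass(matrix)[keep, , drop = FALSE],
                    condition = attr(matrix, "condition"),
                    stage = attr(matrix, "stage"))
}
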