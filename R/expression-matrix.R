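#' Construct an expression matrix
#'
#' A light container for gene-by-sample expression values: a numeric matrix
#' with unique gene ids as row names and sample ids as column names, carrying
#' a biological condition label (e.g. `"WT"`, `"MyD88KO"`) and a stage tag
#' recording what the values are on entry (`"raw"` for FPKM-like or count
#' data, `"normalized"` after count normalization, `"zscore"` after
#' per-gene z-normalization).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param condition single string labelling the biological condition.
#' @param stage one of `"raw"`, `"normalized"`, `"zscore"`.
#' @return an `expr_matrix` object (a numeric matrix with attributes
#'   `condition` and `stage`).
#' @export
expression_matrix <- function(values, condition, stage = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (!is.character(condition) || length(condition) != 1)
    stop("`condition` must be a single string")
  stage <- match.arg(stage, c("raw", "normalized", "zscore"))
  structure(values, condition = condition, stage = stage,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, condition '%s', stage '%s'\n",
              nrow(x), ncol(x), attr(x, "condition"), attr(x, "stage")))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x object to test.
#' @export
is_expression_matrix <- function(x) inherits(x, "expr_matrix")

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids and one row per gene with the gene id
#' in the first column. Malformed rows, non-numeric cells and duplicated gene
#' ids are errors naming the offending gene/cell.
#'
#' @param path path to a TSV file.
#' @param condition condition label to attach (supplied out-of-band; the file
#'   format does not carry it).
#' @param stage stage tag of the stored values (default `"raw"`).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, condition, stage = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  # header may or may not carry a label for the gene-id column
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("malformed row %d (expected %d fields, got %d)",
                 bad + 1L, widths[1], widths[bad]))
  }
  n_samples <- widths[1] - 1L
  sample_ids <- if (length(header) == n_samples + 1L) header[-1]
  else if (length(header) == n_samples) header
  else stop(sprintf(
    "malformed header: %d sample ids for rows with %d value fields",
    length(header), n_samples))
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- matrix(NA_real_, length(gene_ids), n_samples,
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                   body[[i]][j + 1L], gene_ids[i], sample_ids[j]))
    }
    vals[i, ] <- v
  }
  expression_matrix(vals, condition = condition, stage = stage)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written at full double precision (round-trips through
#' [read_expression()] reproduce them exactly to printed precision). Optional
#' header comment lines (prefixed `#`) are skipped on re-reading.
#'
#' @param matrix an [expression_matrix()].
#' @param path output file path.
#' @param header_lines optional character vector of comment lines to prepend
#'   (written with a leading `"# "`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, header_lines = NULL) {
  stopifnot(is_expression_matrix(matrix))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i],
            format(matrix[i, ], digits = 17, trim = TRUE, scientific = NA)),
          collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}
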