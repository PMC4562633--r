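#' Overrepresentation analysis against a fixed background
#'
#' Tests each term gene set for overrepresentation in a query gene list
#' using the one-sided (upper-tail) hypergeometric test, with the background
#' fixed to the supplied universe — in the shared-neighbor workflow this is
#' the predictor pool Pi, never the whole genome. Term sets are intersected
#' with the background before testing; terms with zero overlap are reported
#' (not dropped) so the FDR denominator is reproducible. P-values are
#' adjusted with the Benjamini-Hochberg step-up procedure across all tested
#' terms and rows are sorted by p-value.
#'
#' For a term with `K` background genes, query size `n`, background size `M`
#' and overlap `k`, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(M, K, n)`.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `background`.
#' @param background character vector of gene ids (the pool Pi).
#' @param terms a [gene_set_collection()].
#' @param min_term_size terms with fewer background genes are skipped
#'   (default 1, i.e. none skipped).
#' @return data.frame with columns `term_id`, `description`, `k`, `K`, `n`,
#'   `M`, `p_value`, `fdr`, `overlap_genes` (comma-separated).
#' @export
overrepresentation <- function(query, background, terms, min_term_size = 1) {
  stopifnot(inherits(terms, "gene_set_collection"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query genes outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  M <- length(background)
  n <- length(query)
  rows <- lapply(names(terms$sets), function(id) {
    tg <- intersect(terms$sets[[id]]$genes, background)
    K <- length(tg)
    if (K < min_term_size) return(NULL)
    ov <- intersect(query, tg)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term_id = id, description = terms$sets[[id]]$description,
               k = k, K = K, n = n, M = M, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows))
    return(data.frame(term_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      M = integer(), p_value = numeric(), fdr = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  rows$fdr <- stats::p.adjust(rows$p_value, method = "BH")
  rows <- rows[order(rows$p_value, rows$term_id),
               c("term_id", "description", "k", "K", "n", "M", "p_value",
                 "fdr", "overlap_genes")]
  rownames(rows) <- NULL
  rows
}

#' Write an enrichment table as TSV
#'
#' @param table a data.frame from [overrepresentation()].
#' @param path output path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(table, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
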