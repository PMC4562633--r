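#' Correlation-distance baseline configuration
#'
#' The baseline calls a pool gene a neighbor of a pathway when its
#' correlation distance `d = 1 - r` to the nearest pathway gene falls at or
#' below the threshold `mu` (default 0.1). The signed correlation is the
#' default; `absolute = TRUE` uses `d = 1 - |r|`, which also admits strong
#' anti-correlation.
#'
#' @param mu distance threshold in \[0, 2\].
#' @param method `"pearson"` or `"spearman"`.
#' @param absolute use `1 - |r|` instead of `1 - r`.
#' @return a `corr_config` list.
#' @export
corr_config <- function(mu = 0.1, method = c("pearson", "spearman"),
                        absolute = FALSE) {
  stopifnot(mu >= 0, mu <= 2)
  structure(list(mu = mu, method = match.arg(method), absolute = absolute),
            class = "corr_config")
}

#' Correlation-distance neighbor calling (baseline)
#'
#' For every pool gene and each pathway, computes the minimum correlation
#' distance to the pathway's genes and calls a neighbor when it is at or
#' below `mu`. Emits the same result shape as [shared_neighbors()] so both
#' methods can be compared downstream; the edge weight is the correlation
#' coefficient.
#'
#' @inheritParams neighbors_of_pathway
#' @param config a [corr_config()].
#' @return a `neighbor_result` (method `"correlation"`).
#' @export
correlation_neighbors <- function(matrix, pair, config = corr_config()) {
  stopifnot(is_expression_matrix(matrix), inherits(pair, "pathway_pair"))
  pool <- match_pathway_rows(matrix, pair$pool, "predictor-pool")
  vals <- unclass(matrix)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance genes present: ",
         paste(rownames(vals)[sds == 0], collapse = ", "))
  edges <- list()
  for (k in 1:2) {
    chi <- if (k == 1) pair$chi1 else pair$chi2
    chi <- match_pathway_rows(matrix, chi, paste0("pathway-", k))
    r <- stats::cor(t(vals[pool, , drop = FALSE]),
                    t(vals[chi, , drop = FALSE]), method = config$method)
    d <- if (config$absolute) 1 - abs(r) else 1 - r
    hit <- which(d <= config$mu, arr.ind = TRUE)
    if (nrow(hit)) {
      edges[[k]] <- data.frame(
        which_pathway = k,
        pathway_gene = chi[hit[, 2]],
        neighbor_gene = pool[hit[, 1]],
        weight = r[hit],
        penalty = NA_real_, variance_explained = NA_real_,
        met_target = NA, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, c(edges[!vapply(edges, is.null, TRUE)],
                            list(empty_edges())))
  neighbor_result(attr(matrix, "condition"), pair, edges,
                  method = "correlation")
}
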