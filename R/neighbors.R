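#' Neighbor-calling results
#'
#' Internal constructor for the common result shape shared by the elastic-net
#' method and the correlation-distance baseline: an edge table (one row per
#' pathway-gene/neighbor link) plus the derived sets Gamma1, Gamma2 and their
#' intersection (the shared neighbor genes).
#'
#' @param condition condition label of the expression matrix used.
#' @param pair the [build_predictor_pool()] pathway pair.
#' @param edges data.frame with columns `which_pathway` (1 or 2),
#'   `pathway_gene`, `neighbor_gene`, `weight` (elastic-net coefficient or
#'   correlation), `penalty`, `variance_explained`, `met_target` (the last
#'   three are NA for the correlation baseline).
#' @param method `"enet"` or `"correlation"`.
#' @return a `neighbor_result` with fields `condition`, `method`, `pair`,
#'   `edges`, `gamma1`, `gamma2`, `shared`.
#' @keywords internal
neighbor_result <- function(condition, pair, edges, method) {
  gamma1 <- sort(unique(edges$neighbor_gene[edges$which_pathway == 1]))
  gamma2 <- sort(unique(edges$neighbor_gene[edges$which_pathway == 2]))
  stopifnot(all(gamma1 %in% pair$pool), all(gamma2 %in% pair$pool))
  structure(list(condition = condition, method = method, pair = pair,
                 edges = edges, gamma1 = gamma1, gamma2 = gamma2,
                 shared = intersect(gamma1, gamma2)),
            class = "neighbor_result")
}

#' @export
print.neighbor_result <- function(x, ...) {
  cat(sprintf(
    "neighbor_result [%s, %s]: |Gamma1| = %d, |Gamma2| = %d, |shared| = %d (%d edges)\n",
    x$condition, x$method, length(x$gamma1), length(x$gamma2),
    length(x$shared), nrow(x$edges)))
  invisible(x)
}

match_pathway_rows <- function(matrix, genes, what) {
  present <- genes[genes %in% rownames(matrix)]
  if (!length(present))
    stop("no ", what, " genes present in the expression matrix")
  present
}

#' Find all neighbor genes of one pathway (Algorithm 1)
#'
#' Models each pathway gene's profile by elastic-net regression on the
#' predictor pool, selects the sparsest model meeting the variance target
#' ([select_coefficients()]), and takes the union of the per-gene neighbor
#' sets. Genes whose path never reaches the target contribute their
#' best-fitting (smallest-penalty) model, flagged `met_target = FALSE` in the
#' edge table.
#'
#' @param matrix a z-scored [expression_matrix()] containing the pathway and
#'   pool genes as rows.
#' @param pair a [build_predictor_pool()] result.
#' @param which 1 or 2: which pathway of the pair to model.
#' @param config an [enet_config()].
#' @return list with `gamma` (character vector, the union neighbor set) and
#'   `edges` (data.frame as in [neighbor_result()]).
#' @export
neighbors_of_pathway <- function(matrix, pair, which, config = enet_config()) {
  stopifnot(is_expression_matrix(matrix), inherits(pair, "pathway_pair"),
            which %in% c(1, 2))
  chi <- if (which == 1) pair$chi1 else pair$chi2
  chi <- match_pathway_rows(matrix, chi, paste0("pathway-", which))
  pool <- match_pathway_rows(matrix, pair$pool, "predictor-pool")
  X <- t(unclass(matrix)[pool, , drop = FALSE])
  edges <- vector("list", length(chi))
  for (i in seq_along(chi)) {
    y <- unclass(matrix)[chi[i], ]
    path <- fit_enet_path(y, X, config, target_gene = chi[i])
    sel <- select_coefficients(path, config$variance_target)
    nb <- neighbors_of_gene(sel$coefficients, config$zero_tol)
    if (length(nb)) {
      edges[[i]] <- data.frame(
        which_pathway = which, pathway_gene = chi[i], neighbor_gene = nb,
        weight = unname(sel$coefficients[nb]), penalty = sel$penalty,
        variance_explained = sel$achieved_variance,
        met_target = sel$met_target, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, c(edges[!vapply(edges, is.null, TRUE)],
                            list(empty_edges())))
  list(gamma = sort(unique(edges$neighbor_gene)), edges = edges)
}

empty_edges <- function() {
  data.frame(which_pathway = integer(), pathway_gene = character(),
             neighbor_gene = character(), weight = numeric(),
             penalty = numeric(), variance_explained = numeric(),
             met_target = logical(), stringsAsFactors = FALSE)
}

#' Find the shared neighbor genes of a pathway pair (Algorithm 2)
#'
#' Runs [neighbors_of_pathway()] for both pathways and intersects the two
#' neighbor sets; the intersection is the set of candidate intermediary
#' genes, each having a non-zero coefficient for at least one gene in each
#' pathway. Full edge provenance is retained.
#'
#' @inheritParams neighbors_of_pathway
#' @return a `neighbor_result` (method `"enet"`).
#' @export
shared_neighbors <- function(matrix, pair, config = enet_config()) {
  n1 <- neighbors_of_pathway(matrix, pair, 1, config)
  n2 <- neighbors_of_pathway(matrix, pair, 2, config)
  neighbor_result(attr(matrix, "condition"), pair,
                  rbind(n1$edges, n2$edges), method = "enet")
}

#' Write a neighbor result to disk
#'
#' Emits the edge table as TSV (columns condition, method, pathway_id,
#' pathway_gene, neighbor_gene, weight, penalty, variance_explained,
#' met_target) and the three derived sets as plain-text gene lists named
#' `<condition>_<pair>_{gamma1,gamma2,shared}.txt`.
#'
#' @param result a `neighbor_result`.
#' @param dir output directory (created if missing).
#' @param header_lines optional `#`-prefixed comment lines for every file.
#' @return character vector of the paths written, invisibly.
#' @export
write_neighbor_result <- function(result, dir, header_lines = NULL) {
  stopifnot(inherits(result, "neighbor_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pair_tag <- paste0(result$pair$name1, "-", result$pair$name2)
  stem <- file.path(dir, paste0(result$condition, "_", pair_tag))
  ed <- result$edges
  tab <- data.frame(condition = rep(result$condition, nrow(ed)),
                    method = rep(result$method, nrow(ed)),
                    pathway_id = ifelse(ed$which_pathway == 1,
                                        result$pair$name1, result$pair$name2),
                    ed[, c("pathway_gene", "neighbor_gene", "weight",
                           "penalty", "variance_explained", "met_target")],
                    stringsAsFactors = FALSE)
  edge_path <- paste0(stem, "_edges.tsv")
  con <- file(edge_path, "w")
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paths <- edge_path
  for (set in c("gamma1", "gamma2", "shared")) {
    p <- paste0(stem, "_", set, ".txt")
    write_gene_list(result[[set]], p, header_lines)
    paths <- c(paths, p)
  }
  invisible(paths)
}
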