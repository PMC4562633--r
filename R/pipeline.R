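#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config) {
  c(paste0("crossnet ", as.character(utils::packageVersion("crossnet"))),
    paste0("config_hash=", config_hash(config)))
}

#' Run the synthetic-data generator and write its outputs
#'
#' Writes one TSV expression matrix per condition, the two pathway gene
#' lists, a `truth.json` with the planted structure, and a `config.yaml`
#' echo of the generator settings.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return the `simulate_crosstalk()` result, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_crosstalk(config)
  hdr <- output_header(unclass(config))
  for (cond in names(sim$matrices))
    write_expression(sim$matrices[[cond]],
                     file.path(out_dir, paste0(cond, "_expression.tsv")), hdr)
  write_gene_list(sim$truth$pathway1_genes,
                  file.path(out_dir, "pathway1_genes.txt"), hdr)
  write_gene_list(sim$truth$pathway2_genes,
                  file.path(out_dir, "pathway2_genes.txt"), hdr)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(unclass(truth), file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(yaml::as.yaml(unclass(config)), file.path(out_dir, "config.yaml"))
  invisible(sim)
}

#' Preprocess raw expression matrices for neighbor calling
#'
#' For FPKM-like data (`mode = "fpkm"`): apply the dynamic-range filter
#' across conditions ([filter_dynamic_genes()]), subset, drop zero-variance
#' genes and z-normalize. For count data (`mode = "counts"`):
#' upper-quartile-normalize each sample, keep genes with at least
#' `min_count` raw reads in every sample, then z-normalize. Writes one
#' matrix per condition plus a `preprocess_report.tsv` of genes dropped at
#' each step.
#'
#' @param matrices named list of raw [expression_matrix()] objects, one per
#'   condition.
#' @param out_dir output directory (optional; if `NULL` nothing is written).
#' @param mode `"fpkm"` or `"counts"`.
#' @param fold,floor dynamic-range thresholds (fpkm mode).
#' @param min_count minimum per-sample read count (counts mode).
#' @return named list of z-scored [expression_matrix()] objects.
#' @export
run_preprocess <- function(matrices, out_dir = NULL, mode = c("fpkm", "counts"),
                           fold = 2, floor = 5, min_count = 1) {
  mode <- match.arg(mode)
  stopifnot(length(matrices) >= 1, all(vapply(matrices, is_expression_matrix, TRUE)))
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, attr, "", "condition")
  n0 <- nrow(matrices[[1]])
  report <- list()
  if (mode == "fpkm") {
    keep <- filter_dynamic_genes(matrices, fold = fold, floor = floor)
    if (!length(keep)) stop("no genes pass the dynamic-range filter")
    report$dynamic_filter <- n0 - length(keep)
    matrices <- lapply(matrices, subset_genes, genes = keep)
  } else {
    raw <- matrices
    matrices <- lapply(matrices, normalize_counts_q75)
    # membership is decided on raw read counts; the normalized values keep
    # their sample-depth-free scale
    keep <- Reduce(intersect, lapply(raw, filter_min_reads,
                                     min_count = min_count))
    if (!length(keep)) stop("no genes pass the minimum-read filter")
    report$min_read_filter <- n0 - length(keep)
    matrices <- lapply(matrices, subset_genes, genes = keep)
  }
  nv <- nrow(matrices[[1]])
  matrices <- lapply(matrices, drop_zero_variance)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("no genes left after zero-variance removal")
  matrices <- lapply(matrices, subset_genes, genes = common)
  report$zero_variance <- nv - length(common)
  matrices <- lapply(matrices, znormalize)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- output_header(list(mode = mode, fold = fold, floor = floor,
                              min_count = min_count))
    for (cond in names(matrices))
      write_expression(matrices[[cond]],
                       file.path(out_dir, paste0(cond, "_zscore.tsv")), hdr)
    rep_df <- data.frame(step = names(report),
                         genes_dropped = unlist(report, use.names = FALSE))
    utils::write.table(rep_df, file.path(out_dir, "preprocess_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  matrices
}

#' Run neighbor calling for every condition
#'
#' Applies [shared_neighbors()] (or [correlation_neighbors()]) to each
#' condition's z-scored matrix against one pathway pair.
#'
#' @param matrices named list of z-scored [expression_matrix()] objects.
#' @param pair a [build_predictor_pool()] pathway pair.
#' @param method `"enet"` or `"correlation"`.
#' @param enet an [enet_config()].
#' @param corr a [corr_config()].
#' @param out_dir optional output directory for [write_neighbor_result()]
#'   files.
#' @return named list of `neighbor_result` objects.
#' @export
run_neighbors <- function(matrices, pair, method = c("enet", "correlation"),
                          enet = enet_config(), corr = corr_config(),
                          out_dir = NULL) {
  method <- match.arg(method)
  stopifnot(all(vapply(matrices, is_expression_matrix, TRUE)))
  results <- lapply(matrices, function(m) {
    if (method == "enet") shared_neighbors(m, pair, enet)
    else correlation_neighbors(m, pair, corr)
  })
  if (!is.null(out_dir)) {
    hdr <- output_header(list(method = method, enet = unclass(enet),
                              corr = unclass(corr)))
    for (r in results) write_neighbor_result(r, out_dir, hdr)
  }
  results
}

#' Compare per-condition neighbor sets and write Venn regions
#'
#' @inheritParams compare_conditions
#' @param out_dir optional output directory for [write_comparison()].
#' @return a `condition_comparison`.
#' @export
run_compare <- function(results, set = "shared", out_dir = NULL) {
  cmp <- compare_conditions(results, set = set)
  if (!is.null(out_dir))
    write_comparison(cmp, out_dir, output_header(list(set = set)))
  cmp
}

#' Run overrepresentation analysis for each Venn region
#'
#' The background is the run's predictor pool Pi (taken from the pathway
#' pair), never the whole genome.
#'
#' @param comparison a [venn_regions()] result over pool-gene sets.
#' @param pair the [build_predictor_pool()] pathway pair defining Pi.
#' @param terms a [gene_set_collection()] of annotation terms.
#' @param out_dir optional output directory; one TSV per region.
#' @return named list of enrichment data.frames, one per non-empty region.
#' @export
run_enrich <- function(comparison, pair, terms, out_dir = NULL) {
  stopifnot(inherits(comparison, "condition_comparison"),
            inherits(pair, "pathway_pair"))
  out <- list()
  for (r in names(comparison$regions)) {
    genes <- comparison$regions[[r]]
    if (!length(genes)) next
    out[[r]] <- overrepresentation(genes, pair$pool, terms)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- output_header(list(background = "predictor_pool",
                              pool_size = length(pair$pool)))
    for (r in names(out)) {
      safe <- gsub("\\\\", "_not_", gsub("&", "_and_", r))
      write_enrichment(out[[r]],
                       file.path(out_dir, paste0("enrichment_", safe, ".tsv")),
                       hdr)
    }
  }
  out
}
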