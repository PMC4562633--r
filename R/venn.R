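#' Partition gene sets from several conditions into Venn regions
#'
#' Assigns every gene in the union of the per-condition sets to exactly one
#' region keyed by its membership signature. Region labels are canonical:
#' member conditions sorted and joined by `"&"`, followed by `"\\X"` for each
#' sorted non-member condition (e.g. with conditions W, M, T a gene present
#' in W and T only gets `"T&W\\M"`). The regions are pairwise disjoint and
#' cover the union; this partition property is asserted on every call.
#'
#' @param sets named list (2 or more conditions) of character vectors of
#'   gene ids.
#' @return a `condition_comparison`: list with `sets` (the inputs,
#'   deduplicated), `conditions`, and `regions` (named list of gene
#'   vectors).
#' @export
venn_regions <- function(sets) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a non-empty named list of gene vectors")
  if (length(sets) < 2) stop("need at least 2 conditions")
  conds <- sort(names(sets))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(conds, function(cn) universe %in% sets[[cn]],
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(m) {
    lab <- paste(conds[m], collapse = "&")
    if (any(!m)) lab <- paste0(lab, paste0("\\", conds[!m], collapse = ""))
    lab
  })
  regions <- split(universe, sig)
  # partition property: disjoint by construction of split; assert coverage
  stopifnot(sum(lengths(regions)) == length(universe),
            !anyDuplicated(unlist(regions, use.names = FALSE)))
  structure(list(sets = sets, conditions = conds, regions = regions),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("condition_comparison over", paste(x$conditions, collapse = ", "), "\n")
  for (r in names(x$regions))
    cat(sprintf("  %-24s %d genes\n", r, length(x$regions[[r]])))
  invisible(x)
}

#' Extract the genes in one Venn region by membership
#'
#' Convenience accessor for regions like "in A and B but not C": genes
#' present in every condition of `within` and absent from every condition of
#' `without`. Conditions named in neither argument are unconstrained.
#'
#' @param comparison a [venn_regions()] result.
#' @param within conditions the genes must belong to.
#' @param without conditions the genes must not belong to; defaults to all
#'   remaining conditions (i.e. the exact Venn region).
#' @return character vector of gene ids.
#' @export
region_genes <- function(comparison, within,
                         without = setdiff(comparison$conditions, within)) {
  stopifnot(inherits(comparison, "condition_comparison"),
            all(within %in% comparison$conditions),
            all(without %in% comparison$conditions))
  g <- Reduce(intersect, comparison$sets[within])
  for (cn in without) g <- setdiff(g, comparison$sets[[cn]])
  sort(g)
}

#' Compare neighbor results across conditions
#'
#' Collects one gene set per condition from a list of `neighbor_result`
#' objects and partitions them into Venn regions. For knockout designs the
#' shared sets localize intermediaries lost with either branch (the default);
#' `set = "gamma1"` instead compares the neighbor sets of pathway 1 alone,
#' which localizes genes whose association with that single pathway depends
#' on a condition.
#'
#' @param results list of `neighbor_result` objects with distinct conditions.
#' @param set which per-condition set to compare: `"shared"`, `"gamma1"` or
#'   `"gamma2"`.
#' @return a `condition_comparison` (see [venn_regions()]).
#' @export
compare_conditions <- function(results, set = c("shared", "gamma1", "gamma2")) {
  set <- match.arg(set)
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, TRUE, "neighbor_result")))
  conds <- vapply(results, `[[`, character(1), "condition")
  if (anyDuplicated(conds)) stop("duplicate condition labels in results")
  sets <- lapply(results, `[[`, set)
  names(sets) <- conds
  venn_regions(sets)
}

#' Write a condition comparison to disk
#'
#' One plain-text gene list per region plus a `regions.tsv` summary
#' (columns region, size).
#'
#' @param comparison a [venn_regions()] result.
#' @param dir output directory.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return paths written, invisibly.
#' @export
write_comparison <- function(comparison, dir, header_lines = NULL) {
  stopifnot(inherits(comparison, "condition_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (r in names(comparison$regions)) {
    safe <- gsub("\\\\", "_not_", gsub("&", "_and_", r))
    p <- file.path(dir, paste0("region_", safe, ".txt"))
    write_gene_list(comparison$regions[[r]], p, header_lines)
    paths <- c(paths, p)
  }
  summ <- data.frame(region = names(comparison$regions),
                     size = lengths(comparison$regions))
  p <- file.path(dir, "regions.tsv")
  con <- file(p, "w")
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(summ, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(paths, p))
}
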