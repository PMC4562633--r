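#' Build the predictor pool for a pathway pair
#'
#' Given the expression universe Omega and two disjoint pathway gene sets
#' chi1 and chi2, the predictor pool Pi is every gene outside both pathways:
#' `Pi = (Omega \ chi1) intersect (Omega \ chi2)`. Pathway genes absent from
#' the universe are dropped with a warning reporting how many.
#'
#' @param universe character vector of all gene ids (Omega), e.g.
#'   `rownames()` of the filtered expression matrix.
#' @param chi1,chi2 character vectors of pathway gene ids. Must be disjoint;
#'   overlap is an error (no silent fixing).
#' @param name1,name2 pathway names used in output labels.
#' @return a `pathway_pair` object with fields `name1`, `name2`, `chi1`,
#'   `chi2` (present pathway genes) and `pool` (Pi, in universe order).
#' @export
build_predictor_pool <- function(universe, chi1, chi2,
                                 name1 = "pathway1", name2 = "pathway2") {
  universe <- as.character(universe)
  chi1 <- unique(as.character(chi1))
  chi2 <- unique(as.character(chi2))
  ov <- intersect(chi1, chi2)
  if (length(ov))
    stop("pathway gene sets overlap: ", paste(ov, collapse = ", "))
  absent <- sum(!chi1 %in% universe) + sum(!chi2 %in% universe)
  chi1 <- chi1[chi1 %in% universe]
  chi2 <- chi2[chi2 %in% universe]
  if (absent > 0)
    warning(absent, " pathway gene(s) absent from the expression universe were dropped")
  if (!length(chi1) || !length(chi2))
    stop("a pathway is empty after matching against the universe")
  pool <- setdiff(universe, c(chi1, chi2))
  if (!length(pool)) stop("predictor pool is empty (pathways cover the universe)")
  structure(list(name1 = name1, name2 = name2,
                 chi1 = chi1, chi2 = chi2, pool = pool),
            class = "pathway_pair")
}

#' @export
print.pathway_pair <- function(x, ...) {
  cat(sprintf("pathway_pair '%s' (%d genes) vs '%s' (%d genes); pool %d genes\n",
              x$name1, length(x$chi1), x$name2, length(x$chi2), length(x$pool)))
  invisible(x)
}
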