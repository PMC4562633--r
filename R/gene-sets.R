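#' Gene set collections
#'
#' A named list of gene sets, each with a description and a character vector
#' of gene ids. Gene ids are plain strings, matched exactly and
#' case-sensitively throughout the package.
#'
#' @param sets named list; each element is a list with fields `description`
#'   (string) and `genes` (character vector, non-empty, no duplicates).
#' @param name collection name.
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, name = "collection") {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a non-empty named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate term ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  for (id in names(sets)) {
    s <- sets[[id]]
    if (!is.list(s) || is.null(s$genes)) stop("set '", id, "' lacks a `genes` field")
    if (!length(s$genes)) stop("empty gene set: '", id, "'")
    sets[[id]]$genes <- unique(as.character(s$genes))
    if (is.null(s$description)) sets[[id]]$description <- ""
  }
  structure(list(name = name, sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets (sizes %s)\n", x$name,
              length(x$sets),
              paste(range(vapply(x$sets, function(s) length(s$genes), 1L)),
                    collapse = "-")))
  invisible(x)
}

#' Read gene sets from GMT or plain-text files
#'
#' GMT lines are `term<TAB>description<TAB>gene1<TAB>gene2...`. A file whose
#' lines contain no tabs is read as a plain one-gene-per-line list and becomes
#' a single set named after the file. Empty sets and duplicate term ids are
#' errors.
#'
#' @param path path to a `.gmt` file or a plain gene list.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop("no gene sets in file: ", path)
  if (!any(grepl("\t", lines, fixed = TRUE))) {
    nm <- sub("\\.[^.]*$", "", basename(path))
    sets <- list(list(description = "", genes = lines))
    names(sets) <- nm
    return(gene_set_collection(sets, name = nm))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3 || !any(nzchar(f[-(1:2)])))
      stop("empty gene set at line ", i, ": '", ids[i], "'")
    list(description = f[2], genes = f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- ids
  gene_set_collection(sets, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a gene list as plain text, one gene per line
#'
#' @param genes character vector of gene ids.
#' @param path output path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(as.character(genes), con)
  invisible(path)
}
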