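#' Gene-set library
#'
#' Named collection of gene sets (GO/KEGG-style terms) with an explicit
#' universe used as the background population in over-representation tests.
#'
#' @param sets named list; each element is a list with `description` (string)
#'   and `genes` (character vector, uppercased on construction).
#' @param name library label.
#' @param universe background gene set; defaults to the union of all sets.
#' @return Object of class `GeneSetLibrary`.
#' @export
GeneSetLibrary <- function(sets, name = "library", universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a non-empty named list")
  sets <- lapply(sets, function(s) {
    genes <- unique(toupper(as.character(s$genes)))
    if (!length(genes)) stop("empty gene set in library")
    list(description = as.character(s$description %||% ""), genes = genes)
  })
  all_genes <- sort(unique(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE)))
  if (is.null(universe)) {
    universe <- all_genes
  } else {
    universe <- sort(unique(toupper(as.character(universe))))
    out <- setdiff(all_genes, universe)
    if (length(out))
      stop("library genes missing from explicit universe: ",
           paste(utils::head(out, 5), collapse = ", "))
  }
  structure(list(name = as.character(name), sets = sets, universe = universe),
            class = "GeneSetLibrary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.GeneSetLibrary <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1))
  cat(sprintf("GeneSetLibrary '%s': %d sets (sizes %d-%d), universe %d genes\n",
              x$name, length(x$sets), min(sizes), max(sizes), length(x$universe)))
  invisible(x)
}
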