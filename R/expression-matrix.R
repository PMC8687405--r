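#' Expression matrix container
#'
#' Bundles a genes x samples intensity matrix with its case/control design and
#' a scale flag so that downstream steps can refuse inputs on the wrong scale
#' (fold changes are only meaningful on log2 intensities, never on z-scores).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are internal row keys (probe ids, or symbols when already collapsed) and
#'   must be unique; column names are sample ids.
#' @param groups named character vector mapping every sample id to `"case"` or
#'   `"control"`.
#' @param condition_id label for the condition (e.g. `"CMP"`, `"AG"`).
#' @param gene_ids character vector of gene symbols, one per row, uppercased.
#'   May contain duplicates until probes are collapsed (see
#'   [collapse_probes()]). Defaults to the row names.
#' @param scale one of `"raw"`, `"log2"`, `"zscore"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `condition_id`, `values`, `gene_ids`, `groups`, `scale`.
#' @export
ExpressionMatrix <- function(values, groups, condition_id = "condition",
                             gene_ids = rownames(values), scale = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  m <- structure(
    list(condition_id = as.character(condition_id),
         values = values,
         gene_ids = toupper(as.character(gene_ids)),
         groups = groups,
         scale = scale),
    class = "ExpressionMatrix")
  validate_expression_matrix(m)
  m
}

#' Validate an ExpressionMatrix
#'
#' Checks the structural invariants: matching dimensions, unique row keys and
#' sample ids, a complete group map with both groups present, a known scale
#' flag, and no missing values (cells marked NA are rejected rather than
#' imputed).
#'
#' @param m an [ExpressionMatrix()].
#' @param require_groups_n minimum samples per group to demand (default 0; DEG
#'   calling demands 2).
#' @return `m`, invisibly, or an error.
#' @export
validate_expression_matrix <- function(m, require_groups_n = 0L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (length(m$gene_ids) != nrow(v))
    stop("gene_ids length (", length(m$gene_ids), ") != row count (", nrow(v), ")")
  if (anyDuplicated(rownames(v)))
    stop("duplicate row keys: ", paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample ids: ", paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (any(!is.finite(v)))
    stop("non-finite or missing expression values are not permitted (first at row '",
         rownames(v)[which(!is.finite(v), arr.ind = TRUE)[1, 1]], "')")
  if (!m$scale %in% c("raw", "log2", "zscore"))
    stop("unknown scale flag: ", m$scale)
  g <- m$groups
  if (is.null(names(g))) stop("`groups` must be a named vector (sample -> group)")
  missing_grp <- setdiff(colnames(v), names(g))
  if (length(missing_grp))
    stop("samples missing from group map: ", paste(missing_grp, collapse = ", "))
  bad <- setdiff(unique(unname(g[colnames(v)])), c("case", "control"))
  if (length(bad)) stop("group labels must be 'case'/'control', got: ", paste(bad, collapse = ", "))
  if (require_groups_n > 0) {
    tab <- table(factor(g[colnames(v)], levels = c("case", "control")))
    if (any(tab < require_groups_n))
      stop("need at least ", require_groups_n, " case and ", require_groups_n,
           " control samples, got ", tab[["case"]], "/", tab[["control"]])
  }
  invisible(m)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  grp <- table(x$groups[colnames(x$values)])
  cat(sprintf("ExpressionMatrix '%s': %d rows (%d distinct genes) x %d samples [%s case / %s control], scale=%s\n",
              x$condition_id, nrow(x$values), length(unique(x$gene_ids)),
              ncol(x$values),
              if ("case" %in% names(grp)) grp[["case"]] else 0,
              if ("control" %in% names(grp)) grp[["control"]] else 0,
              x$scale))
  invisible(x)
}

#' Case and control sample ids of an ExpressionMatrix
#' @param m an [ExpressionMatrix()].
#' @return list with character vectors `case` and `control`.
#' @export
sample_groups <- function(m) {
  g <- m$groups[colnames(m$values)]
  list(case = names(g)[g == "case"], control = names(g)[g == "control"])
}
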