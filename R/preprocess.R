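#' Log2-transform an expression matrix
#'
#' Microarray intensities are tested and fold-changed on the log2 scale; this
#' replaces every cell by `log2(value + offset)`.
#'
#' @param m an [ExpressionMatrix()] with `scale = "raw"`.
#' @param offset non-negative pseudo-count added before taking logs
#'   (default 1), guarding against zeros.
#' @return The matrix with transformed values and `scale = "log2"`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "raw") stop("log2_transform expects scale='raw', got '", m$scale, "'")
  if (offset < 0) stop("offset must be non-negative")
  shifted <- m$values + offset
  if (any(shifted <= 0)) {
    i <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive value at gene '", rownames(m$values)[i[1]],
         "', sample '", colnames(m$values)[i[2]], "' with offset ", offset)
  }
  m$values <- log2(shifted)
  m$scale <- "log2"
  m
}

#' Z-score normalisation
#'
#' Standardises expression so values are comparable across platforms and
#' cohorts: each gene row (default) is centred on its mean and divided by its
#' standard deviation (sample convention, n-1), giving rows of mean 0 and
#' SD 1. Constant rows cannot be standardised; they are excluded from the
#' output and reported, never NaN-filled. A per-sample (column) variant is
#' available via `margin = "sample"`.
#'
#' @param m an [ExpressionMatrix()] with at least 2 samples.
#' @param margin `"gene"` (rows, default) or `"sample"` (columns).
#' @return The standardised matrix with `scale = "zscore"` and an attribute
#'   `excluded` listing the constant row keys that were dropped (gene margin
#'   only).
#' @export
zscore_rows <- function(m, margin = c("gene", "sample")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  margin <- match.arg(margin)
  v <- m$values
  if (ncol(v) < 2) stop("z-scoring needs at least 2 samples")
  if (margin == "gene") {
    mu <- rowMeans(v)
    sd <- apply(v, 1, stats::sd)
    excluded <- rownames(v)[sd == 0]
    keep <- sd > 0
    if (!any(keep)) stop("all rows are constant; nothing to standardise")
    v <- (v[keep, , drop = FALSE] - mu[keep]) / sd[keep]
    m$gene_ids <- m$gene_ids[keep]
  } else {
    mu <- colMeans(v)
    sd <- apply(v, 2, stats::sd)
    if (any(sd == 0)) stop("constant sample column(s): ",
                           paste(colnames(v)[sd == 0], collapse = ", "))
    v <- sweep(sweep(v, 2, mu, "-"), 2, sd, "/")
    excluded <- character(0)
  }
  m$values <- v
  m$scale <- "zscore"
  attr(m, "excluded") <- excluded
  m
}

#' Collapse probes to gene symbols
#'
#' Cross-platform symbol-level comparison requires one row per gene.
#' `method = "max_abs_t"` keeps, per symbol, the probe whose pooled two-sample
#' t statistic (case vs control) has the largest absolute value — the probe
#' most responsive to the contrast; `method = "mean"` averages the probe rows.
#' Probes absent from the map are dropped with a logged count.
#'
#' @param m an [ExpressionMatrix()]; row keys are probe ids.
#' @param probe_map named character vector probe -> symbol (see
#'   [read_probe_map()]), or `NULL` to collapse on the matrix's own
#'   `gene_ids`.
#' @param method `"max_abs_t"` (default; requires >=2 samples per group) or
#'   `"mean"`.
#' @return An [ExpressionMatrix()] with unique `gene_ids` as row keys and an
#'   attribute `n_unmapped` (probes dropped).
#' @export
collapse_probes <- function(m, probe_map = NULL, method = c("max_abs_t", "mean")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  method <- match.arg(method)
  v <- m$values
  if (is.null(probe_map)) {
    symbols <- m$gene_ids
    mapped <- rep(TRUE, nrow(v))
  } else {
    mapped <- rownames(v) %in% names(probe_map)
    symbols <- character(nrow(v))
    symbols[mapped] <- unname(probe_map[rownames(v)[mapped]])
  }
  n_unmapped <- sum(!mapped)
  if (n_unmapped) message(n_unmapped, " probe(s) not in map, dropped")
  v <- v[mapped, , drop = FALSE]
  symbols <- toupper(symbols[mapped])
  if (!nrow(v)) stop("no probes left after mapping")

  if (method == "max_abs_t") {
    validate_expression_matrix(m, require_groups_n = 2L)
    sg <- sample_groups(m)
    tt <- row_t_statistics(v, sg$case, sg$control)$t
    score <- abs(tt)
    score[!is.finite(score)] <- -Inf   # degenerate probes lose ties
    ord <- order(symbols, -score, rownames(v))
    v <- v[ord, , drop = FALSE]
    symbols <- symbols[ord]
    keep <- !duplicated(symbols)
    out <- v[keep, , drop = FALSE]
    rownames(out) <- symbols[keep]
  } else {
    out <- rowsum(v, group = symbols, reorder = TRUE) /
      as.vector(table(symbols)[sort(unique(symbols))])
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  res <- ExpressionMatrix(out, groups = m$groups, condition_id = m$condition_id,
                          gene_ids = rownames(out), scale = m$scale)
  attr(res, "n_unmapped") <- n_unmapped
  res
}
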