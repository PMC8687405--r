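#' Pooled two-sample t-test
#'
#' Classic unpaired Student t-test with pooled variance: for groups of sizes
#' n1, n2,
#' \deqn{t = \frac{\bar{x}_1 - \bar{x}_2}{s_p \sqrt{1/n_1 + 1/n_2}}, \qquad
#'       s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},}
#' with df = n1 + n2 - 2 and a two-sided p-value from the t distribution.
#'
#' @param case,control numeric vectors, each of length >= 2, all finite.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(case, control) {
  if (length(case) < 2 || length(control) < 2)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(case)) || any(!is.finite(control)))
    stop("non-finite values in input")
  n1 <- length(case); n2 <- length(control)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) / df
  if (sp2 == 0) {
    if (mean(case) == mean(control))
      stop("zero pooled variance with equal means: degenerate gene")
    return(list(t = Inf * sign(mean(case) - mean(control)), df = df, p = 0))
  }
  t <- (mean(case) - mean(control)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Vectorised pooled t over matrix rows. Returns t, df, p, logFC (case-control
# row-mean difference) and a logical `degenerate` flag for zero-pooled-variance
# rows (t/p set NA there).
row_t_statistics <- function(values, case_ids, control_ids) {
  x <- values[, case_ids, drop = FALSE]
  y <- values[, control_ids, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n1 - 1)
  vy <- rowSums((y - my)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / df
  degenerate <- sp2 == 0
  t <- (mx - my) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, logFC = mx - my, degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort the m p-values ascending,
#' compute p_(i) * m / i, enforce monotonicity by a cumulative minimum from
#' the largest rank down, clip at 1, and return values in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Call differentially expressed genes
#'
#' Per-gene pooled two-sample t-test of case vs control on log2 intensities,
#' Benjamini-Hochberg correction across all testable genes, and the standard
#' dual filter: a gene is significant iff `p_adj < alpha` and
#' `|logFC| > lfc` (both strict). logFC is the difference of log2 group means
#' (case minus control). Zero-variance genes cannot be tested; they are
#' reported in the result, never silently dropped.
#'
#' @param m an [ExpressionMatrix()] with `scale = "log2"`, unique gene ids
#'   (collapse probes first) and >= 2 samples per group.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1.0).
#' @return Object of class `DEGSet`: list with `condition_id`, `table`
#'   (data.frame gene/logFC/t/df/p/p_adj/direction/significant over all tested
#'   genes), `up` and `down` significant gene sets, `thresholds`, and
#'   `degenerate` (untestable zero-variance genes).
#' @export
call_degs <- function(m, alpha = 0.05, lfc = 1.0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "log2")
    stop("call_degs expects scale='log2' (fold changes are log2 differences), got '",
         m$scale, "'")
  if (anyDuplicated(m$gene_ids))
    stop("duplicate gene ids; collapse probes before calling DEGs")
  validate_expression_matrix(m, require_groups_n = 2L)
  sg <- sample_groups(m)
  st <- row_t_statistics(m$values, sg$case, sg$control)

  genes <- m$gene_ids
  degenerate <- genes[st$degenerate]
  ok <- !st$degenerate
  tab <- data.frame(gene = genes[ok],
                    logFC = st$logFC[ok],
                    t = st$t[ok],
                    df = st$df,
                    p = st$p[ok],
                    stringsAsFactors = FALSE)
  tab$p_adj <- benjamini_hochberg(tab$p)
  tab$direction <- ifelse(tab$logFC > 0, "up", "down")
  tab$significant <- tab$p_adj < alpha & abs(tab$logFC) > lfc
  tab <- tab[order(tab$p_adj, tab$p, tab$gene), ]
  rownames(tab) <- NULL

  structure(list(condition_id = m$condition_id,
                 table = tab,
                 up = sort(tab$gene[tab$significant & tab$direction == "up"]),
                 down = sort(tab$gene[tab$significant & tab$direction == "down"]),
                 thresholds = c(alpha = alpha, lfc = lfc),
                 degenerate = sort(degenerate)),
            class = "DEGSet")
}

#' Construct a DEGSet from explicit gene sets
#'
#' Convenience constructor used when only the significant sets matter (e.g.
#' truth manifests or externally called lists).
#'
#' @param condition_id condition label.
#' @param up,down character vectors of significant up-/down-regulated genes
#'   (must be disjoint).
#' @param thresholds named numeric `c(alpha=, lfc=)`.
#' @return A `DEGSet` with an empty statistics table.
#' @export
deg_set <- function(condition_id, up, down,
                    thresholds = c(alpha = 0.05, lfc = 1.0)) {
  up <- sort(unique(toupper(up))); down <- sort(unique(toupper(down)))
  if (length(intersect(up, down)))
    stop("up and down sets overlap: ", paste(intersect(up, down), collapse = ", "))
  structure(list(condition_id = condition_id,
                 table = data.frame(),
                 up = up, down = down,
                 thresholds = thresholds, degenerate = character(0)),
            class = "DEGSet")
}

#' @export
print.DEGSet <- function(x, ...) {
  cat(sprintf("DEGSet '%s': %d up, %d down (alpha=%g, |logFC|>%g; %d tested, %d degenerate)\n",
              x$condition_id, length(x$up), length(x$down),
              x$thresholds[["alpha"]], x$thresholds[["lfc"]],
              nrow(x$table), length(x$degenerate)))
  invisible(x)
}

#' @export
summary.DEGSet <- function(object, n = 10, ...) {
  print(object)
  if (nrow(object$table)) {
    cat("Top genes by adjusted p:\n")
    print(utils::head(object$table, n), digits = 4)
  }
  invisible(object)
}

#' All significant genes of a DEGSet
#' @param x a `DEGSet`.
#' @return sorted character vector, union of up and down sets.
#' @export
deg_genes <- function(x) sort(union(x$up, x$down))

#' Write a DEG statistics table as TSV
#' @param degs a `DEGSet` from [call_degs()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(degs, path) {
  utils::write.table(degs$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
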