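#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least k annotated genes when n genes are drawn without replacement from a
#' universe of N genes of which K carry the annotation. Exact (no normal
#' approximation); this is the one-sided over-representation test behind
#' Fisher-exact-style enrichment.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K annotated genes in the universe (term size).
#' @param n query size.
#' @param N universe size.
#' @return the exact upper-tail probability.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts: k=", k, " K=", K, " n=", n, " N=", N)
  if (k == 0) return(1.0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests each term of a library for over-representation in a query gene set
#' using the exact upper-tail hypergeometric probability, with
#' Benjamini-Hochberg correction across all tested terms of the library.
#' Terms with no query overlap are tested too (p = 1) so the correction
#' denominator is the whole library; only terms with overlap >= `min_overlap`
#' are returned.
#'
#' @param query character vector of gene symbols (duplicates and case
#'   ignored).
#' @param lib a [GeneSetLibrary()].
#' @param universe background gene set; defaults to the library's universe.
#'   Query and terms are restricted to it before testing.
#' @param min_overlap minimum overlap for a term to be reported (default 1).
#' @return data.frame with columns `term_id`, `description`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `overlap_genes` (comma-joined), sorted by `p_adj`,
#'   then `p`, then `term_id`.
#' @export
enrich <- function(query, lib, universe = NULL, min_overlap = 1L) {
  stopifnot(inherits(lib, "GeneSetLibrary"))
  query <- unique(toupper(as.character(query)))
  if (!length(query)) stop("empty query gene set")
  universe <- if (is.null(universe)) lib$universe else
    sort(unique(toupper(as.character(universe))))
  q <- intersect(query, universe)
  if (!length(q))
    stop("query has no overlap with the universe (", length(query),
         " genes supplied)")
  N <- length(universe)
  n <- length(q)
  rows <- lapply(names(lib$sets), function(id) {
    term <- intersect(lib$sets[[id]]$genes, universe)
    ov <- intersect(q, term)
    data.frame(term_id = id, description = lib$sets[[id]]$description,
               k = length(ov), K = length(term), n = n, N = N,
               p = hypergeom_upper(length(ov), length(term), n, N),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- benjamini_hochberg(res$p)
  res <- res[res$k >= min_overlap, , drop = FALSE]
  res <- res[order(res$p_adj, res$p, res$term_id),
             c("term_id", "description", "k", "K", "n", "N", "p", "p_adj",
               "overlap_genes")]
  rownames(res) <- NULL
  res
}

#' Gene-disease association test
#'
#' Hypergeometric over-representation of a DEG set within a curated disease
#' gene list (OMIM/dbGaP-style), used to validate that condition-derived DEGs
#' are enriched for known disease genes. Disease genes outside the universe
#' are dropped with a message. For a batch of conditions, adjust the returned
#' p-values across the batch with [benjamini_hochberg()].
#'
#' @param degs character vector of DEG symbols.
#' @param disease_genes character vector of known disease gene symbols.
#' @param universe background gene set (all measured genes); must be
#'   non-empty.
#' @return one-row data.frame with `k`, `K`, `n`, `N`, `p`, `overlap_genes`.
#' @export
gene_disease_association <- function(degs, disease_genes, universe) {
  universe <- sort(unique(toupper(as.character(universe))))
  if (!length(universe)) stop("empty universe")
  degs <- intersect(unique(toupper(degs)), universe)
  dg <- unique(toupper(disease_genes))
  outside <- setdiff(dg, universe)
  if (length(outside))
    message(length(outside), " disease gene(s) outside the universe dropped")
  dg <- intersect(dg, universe)
  ov <- intersect(degs, dg)
  data.frame(k = length(ov), K = length(dg), n = length(degs),
             N = length(universe),
             p = hypergeom_upper(length(ov), length(dg), length(degs),
                                 length(universe)),
             overlap_genes = paste(sort(ov), collapse = ","),
             stringsAsFactors = FALSE)
}
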