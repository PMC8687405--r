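#' Induce a PPI subnetwork on a gene set
#'
#' Node-induced subgraph: only edges with both endpoints in the query are
#' kept. Queried genes present in the PPI but left without edges are retained
#' as isolated (degree 0) nodes; query genes absent from the PPI are listed in
#' the `unmapped` attribute. First-neighbour expansion (adding every PPI
#' partner of a query gene) is available behind `expand_neighbors` and is off
#' by default.
#'
#' @param ppi an [InteractionNetwork()] of kind `ppi_undirected`.
#' @param genes character vector of query gene symbols.
#' @param expand_neighbors logical; when `TRUE` the node set is enlarged by
#'   the direct PPI neighbours of the query before induction.
#' @return An [InteractionNetwork()] (`ppi_undirected`) with attribute
#'   `unmapped`.
#' @export
induce_subnetwork <- function(ppi, genes, expand_neighbors = FALSE) {
  stopifnot(inherits(ppi, "InteractionNetwork"))
  if (ppi$kind != "ppi_undirected") stop("expected a ppi_undirected network")
  genes <- unique(toupper(genes))
  present <- intersect(genes, ppi$nodes$id)
  unmapped <- setdiff(genes, present)
  keep_nodes <- present
  if (expand_neighbors && length(present)) {
    nb <- union(ppi$edges$to[ppi$edges$from %in% present],
                ppi$edges$from[ppi$edges$to %in% present])
    keep_nodes <- union(present, nb)
  }
  e <- ppi$edges[ppi$edges$from %in% keep_nodes & ppi$edges$to %in% keep_nodes, ,
                 drop = FALSE]
  nodes <- data.frame(id = sort(keep_nodes),
                      class = rep("protein", length(keep_nodes)),
                      stringsAsFactors = FALSE)
  out <- InteractionNetwork(e, kind = "ppi_undirected", nodes = nodes)
  attr(out, "unmapped") <- sort(unmapped)
  out
}

#' Rank hub proteins by degree
#'
#' Orders the network's nodes by degree (the classic hub metric) and returns
#' the top k. Ordering is deterministic: degree descending, then symbol
#' ascending. When the k-th degree is tied beyond position k, all tied nodes
#' are included and the ranking is flagged (`tie_at_k`). Tied degrees share
#' the same rank (min rank convention).
#'
#' @param net an undirected [InteractionNetwork()] with at least one node.
#' @param k number of hubs requested (default 10).
#' @return Object of class `HubRanking`: data.frame `node`, `degree`, `rank`
#'   with attributes `k` and `tie_at_k`.
#' @export
rank_hubs <- function(net, k = 10L) {
  stopifnot(inherits(net, "InteractionNetwork"))
  if (nrow(net$nodes) == 0) stop("empty network")
  deg <- node_degrees(net)
  ord <- order(-deg, names(deg))
  deg <- deg[ord]
  k_eff <- min(k, length(deg))
  cutoff <- deg[k_eff]
  tie_at_k <- k_eff < length(deg) && deg[k_eff + 1] == cutoff
  keep <- if (tie_at_k) which(deg >= cutoff) else seq_len(k_eff)
  out <- data.frame(node = names(deg)[keep], degree = as.integer(deg[keep]),
                    stringsAsFactors = FALSE)
  # min-rank convention: rank = position of the first node in the same tier
  out$rank <- vapply(out$degree, function(d) which(out$degree == d)[1],
                     integer(1))
  rownames(out) <- NULL
  structure(out, k = as.integer(k), tie_at_k = tie_at_k,
            class = c("HubRanking", "data.frame"))
}

#' @export
print.HubRanking <- function(x, ...) {
  cat(sprintf("HubRanking: top %d of requested %d%s\n", nrow(x), attr(x, "k"),
              if (isTRUE(attr(x, "tie_at_k"))) " (tie at cutoff, extended)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Rank regulators by number of DEG targets
#'
#' Scores each transcription factor or miRNA by how many distinct DEGs appear
#' among its known targets (its bipartite degree restricted to the DEG set)
#' and returns the top regulators, tie handling as in [rank_hubs()].
#'
#' @param targets an [InteractionNetwork()] of kind `regulator_bipartite`
#'   (edges regulator -> target gene).
#' @param degs character vector of DEG symbols.
#' @param top_n number of regulators requested (default 5).
#' @param regulator_class label carried in the result (`"TF"` or `"miRNA"`).
#' @return Object of class `RegulatorRanking`: data.frame `regulator`,
#'   `n_targets`, `rank`, `targets` (comma-joined DEG targets); empty with a
#'   warning when no regulator touches any DEG.
#' @export
rank_regulators <- function(targets, degs, top_n = 5L, regulator_class = "TF") {
  stopifnot(inherits(targets, "InteractionNetwork"))
  if (targets$kind != "regulator_bipartite")
    stop("expected a regulator_bipartite network")
  degs <- unique(toupper(degs))
  e <- targets$edges[targets$edges$to %in% degs, , drop = FALSE]
  if (!nrow(e)) {
    warning("no regulator targets any DEG; empty ranking")
    out <- data.frame(regulator = character(), n_targets = integer(),
                      rank = integer(), targets = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, regulator_class = regulator_class,
                     class = c("RegulatorRanking", "data.frame")))
  }
  tgt <- split(e$to, e$from)
  score <- vapply(tgt, function(g) length(unique(g)), integer(1))
  ord <- order(-score, names(score))
  score <- score[ord]; tgt <- tgt[ord]
  n_eff <- min(top_n, length(score))
  cutoff <- score[n_eff]
  tie <- n_eff < length(score) && score[n_eff + 1] == cutoff
  keep <- if (tie) which(score >= cutoff) else seq_len(n_eff)
  out <- data.frame(regulator = names(score)[keep],
                    n_targets = as.integer(score[keep]),
                    stringsAsFactors = FALSE)
  out$rank <- vapply(out$n_targets, function(d) which(out$n_targets == d)[1],
                     integer(1))
  out$targets <- vapply(tgt[keep], function(g) paste(sort(unique(g)), collapse = ","),
                        character(1))
  rownames(out) <- NULL
  structure(out, regulator_class = regulator_class, tie_at_k = tie,
            class = c("RegulatorRanking", "data.frame"))
}

#' @export
print.RegulatorRanking <- function(x, ...) {
  cat(sprintf("RegulatorRanking [%s]: %d regulators\n",
              attr(x, "regulator_class"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Drug-target interactions of a gene set
#'
#' Restricts a drug->target table to the drugs hitting at least one query
#' gene, keeping only their query-gene edges — the protein-drug network of a
#' DEG list.
#'
#' @param drug_targets an [InteractionNetwork()] of kind `drug_bipartite`.
#' @param genes character vector of query gene symbols.
#' @return An [InteractionNetwork()] (`drug_bipartite`); empty when no drug
#'   hits a query gene.
#' @export
drug_interactions <- function(drug_targets, genes) {
  stopifnot(inherits(drug_targets, "InteractionNetwork"))
  if (drug_targets$kind != "drug_bipartite")
    stop("expected a drug_bipartite network")
  genes <- unique(toupper(genes))
  e <- drug_targets$edges[drug_targets$edges$to %in% genes, , drop = FALSE]
  InteractionNetwork(e, kind = "drug_bipartite")
}
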