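#' Interaction network container
#'
#' A light edge-list graph used for every network in the pipeline: the
#' undirected weighted PPI, directed bipartite regulator->target and
#' drug->target tables, and the bipartite condition<->gene diseasome.
#' Undirected edges are stored canonically (`a < b` lexicographically) and
#' deduplicated; self-loops are never stored.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`
#'   (defaults to 1).
#' @param kind one of `"ppi_undirected"`, `"regulator_bipartite"`,
#'   `"drug_bipartite"`, `"diseasome_bipartite"`.
#' @param nodes optional data.frame with columns `id`, `class`; defaults to
#'   the nodes appearing in `edges`. For bipartite kinds the first endpoint
#'   class is `"regulator"`/`"drug"`/`"condition"` and the second `"gene"`.
#' @param check_weights for the PPI kind, reject weights outside \[0, 1\].
#'
#' @return Object of class `InteractionNetwork`: list with `kind`, `nodes`
#'   (data.frame id/class) and `edges` (data.frame from/to/weight).
#' @export
InteractionNetwork <- function(edges, kind, nodes = NULL, check_weights = TRUE) {
  kinds <- c("ppi_undirected", "regulator_bipartite", "drug_bipartite",
             "diseasome_bipartite")
  if (!kind %in% kinds) stop("unknown network kind: ", kind)
  if (is.null(edges)) edges <- data.frame(from = character(), to = character())
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges <- edges[, c("from", "to", "weight")]

  loops <- edges$from == edges$to
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]

  if (kind == "ppi_undirected") {
    if (check_weights && nrow(edges) && any(edges$weight < 0 | edges$weight > 1))
      stop("PPI edge weights must lie in [0, 1]")
    flip <- edges$from > edges$to
    tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  first_class <- switch(kind, regulator_bipartite = "regulator",
                        drug_bipartite = "drug",
                        diseasome_bipartite = "condition", "protein")
  second_class <- if (kind == "ppi_undirected") "protein" else "gene"
  if (is.null(nodes)) {
    nodes <- data.frame(
      id = c(unique(edges$from), setdiff(unique(edges$to), unique(edges$from))),
      class = c(rep(first_class, length(unique(edges$from))),
                rep(second_class, length(setdiff(unique(edges$to), unique(edges$from))))),
      stringsAsFactors = FALSE)
  } else {
    nodes <- data.frame(id = as.character(nodes$id),
                        class = as.character(nodes$class),
                        stringsAsFactors = FALSE)
  }
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  if (kind != "ppi_undirected" && nrow(edges)) {
    cls <- stats::setNames(nodes$class, nodes$id)
    same <- cls[edges$from] == cls[edges$to]
    if (any(same, na.rm = TRUE))
      stop("bipartite network has edges within one node class: ",
           paste(utils::head(edges$from[which(same)], 3), collapse = ", "))
  }

  structure(list(kind = kind, nodes = nodes, edges = edges,
                 n_self_loops_dropped = n_loops),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork [%s]: %d nodes, %d edges\n",
              x$kind, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$class)
    cat("  node classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of edges / nodes
#' @param net an [InteractionNetwork()].
#' @return integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) nrow(net$nodes)

# igraph view of a network; undirected for ppi, directed otherwise.
as_igraph <- function(net) {
  directed <- net$kind %in% c("regulator_bipartite", "drug_bipartite")
  g <- igraph::graph_from_data_frame(net$edges, directed = directed,
                                     vertices = net$nodes)
  g
}

#' Node degrees of a network
#'
#' Degree (number of incident edges) for every node, isolated nodes included
#' with degree 0.
#'
#' @param net an [InteractionNetwork()].
#' @return named integer vector over all nodes.
#' @export
node_degrees <- function(net) {
  if (nrow(net$nodes) == 0) return(stats::setNames(integer(0), character(0)))
  d <- igraph::degree(as_igraph(net), mode = "all")
  stats::setNames(as.integer(d), names(d))[net$nodes$id]
}
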