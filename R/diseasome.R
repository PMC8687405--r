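#' Shared DEGs between a target condition and one risk factor
#'
#' Cross-comparative intersection of two conditions' DEG sets. With
#' `direction_consistent = TRUE` (default) a gene is shared only when
#' dysregulated in the same direction in both conditions (up∩up, down∩down) —
#' matching diseasome networks built separately for up- and down-regulated
#' genes. With `FALSE`, the intersection is at symbol level regardless of
#' direction, split by the target's direction.
#'
#' @param target,factor `DEGSet`s; a warning is issued when their thresholds
#'   differ.
#' @param direction_consistent logical, see above.
#' @return Object of class `DiseasomePair`: list with `target_id`,
#'   `factor_id`, `shared_up`, `shared_down`, `n_shared`.
#' @export
intersect_pair <- function(target, factor, direction_consistent = TRUE) {
  stopifnot(inherits(target, "DEGSet"), inherits(factor, "DEGSet"))
  if (!isTRUE(all.equal(target$thresholds, factor$thresholds)))
    warning("DEG sets were called with different thresholds")
  if (direction_consistent) {
    up <- intersect(target$up, factor$up)
    down <- intersect(target$down, factor$down)
  } else {
    shared <- intersect(deg_genes(target), deg_genes(factor))
    up <- intersect(shared, target$up)
    down <- intersect(shared, target$down)
  }
  structure(list(target_id = target$condition_id,
                 factor_id = factor$condition_id,
                 shared_up = sort(up), shared_down = sort(down),
                 n_shared = length(up) + length(down)),
            class = "DiseasomePair")
}

#' @export
print.DiseasomePair <- function(x, ...) {
  cat(sprintf("DiseasomePair %s ~ %s: %d shared (%d up, %d down)\n",
              x$target_id, x$factor_id, x$n_shared,
              length(x$shared_up), length(x$shared_down)))
  invisible(x)
}

#' Build a direction-specific diseasome network
#'
#' Bipartite condition<->gene graph for one direction of regulation: nodes are
#' the target condition, the risk factors, and every gene of that direction
#' shared between the target and at least one factor. An edge links a
#' condition to a gene iff the gene is a direction-matched DEG of that
#' condition and shared with the target (the target is linked to all its
#' shared genes).
#'
#' @param target `DEGSet` of the target condition.
#' @param factors list of factor `DEGSet`s (at least one).
#' @param direction `"up"` or `"down"`.
#' @param direction_consistent passed to [intersect_pair()].
#' @return An [InteractionNetwork()] of kind `diseasome_bipartite`; empty gene
#'   side (with a warning) when nothing is shared.
#' @export
build_diseasome <- function(target, factors, direction = c("up", "down"),
                            direction_consistent = TRUE) {
  direction <- match.arg(direction)
  if (!length(factors)) stop("need at least one factor DEGSet")
  if (inherits(factors, "DEGSet")) factors <- list(factors)
  slot <- if (direction == "up") "shared_up" else "shared_down"
  edges <- list()
  shared_all <- character(0)
  for (f in factors) {
    pair <- intersect_pair(target, f, direction_consistent)
    genes <- pair[[slot]]
    shared_all <- union(shared_all, genes)
    if (length(genes))
      edges[[f$condition_id]] <- data.frame(from = f$condition_id, to = genes,
                                            stringsAsFactors = FALSE)
  }
  if (length(shared_all))
    edges[[target$condition_id]] <- data.frame(from = target$condition_id,
                                               to = shared_all,
                                               stringsAsFactors = FALSE)
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  cond_ids <- c(target$condition_id,
                vapply(factors, `[[`, character(1), "condition_id"))
  nodes <- data.frame(id = c(cond_ids, sort(shared_all)),
                      class = c(rep("condition", length(cond_ids)),
                                rep("gene", length(shared_all))),
                      stringsAsFactors = FALSE)
  if (!length(shared_all))
    warning("no shared ", direction, "-regulated genes; diseasome has no gene nodes")
  InteractionNetwork(edge_df, kind = "diseasome_bipartite", nodes = nodes)
}

#' Genes shared across multiple conditions
#'
#' Tallies, over all supplied conditions, in how many each gene is a
#' significant DEG (either direction), and reports genes reaching a minimum
#' multiplicity — the multiway-shared genes of the diseasome.
#'
#' @param degsets list of >= 2 `DEGSet`s.
#' @param min_conditions minimum number of conditions (>= 2) a gene must be a
#'   DEG in.
#' @return data.frame of class `SharedGeneReport` with columns `gene`,
#'   `n_conditions`, `conditions` (comma-joined ids), sorted by multiplicity
#'   descending then symbol.
#' @export
multiway_shared <- function(degsets, min_conditions = 2L) {
  if (min_conditions < 2) stop("min_conditions must be at least 2")
  if (length(degsets) < 2) stop("need at least 2 DEG sets")
  ids <- vapply(degsets, `[[`, character(1), "condition_id")
  membership <- lapply(degsets, deg_genes)
  genes <- sort(unique(unlist(membership)))
  hit <- vapply(membership, function(g) genes %in% g,
                logical(length(genes)))
  if (length(genes) == 1) hit <- matrix(hit, nrow = 1)
  counts <- rowSums(hit)
  keep <- counts >= min_conditions
  conds <- apply(hit[keep, , drop = FALSE], 1,
                 function(r) paste(ids[r], collapse = ","))
  out <- data.frame(gene = genes[keep],
                    n_conditions = as.integer(counts[keep]),
                    conditions = if (length(conds)) conds else character(0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_conditions, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("SharedGeneReport", "data.frame")
  out
}

#' Pairwise shared-DEG summary table
#'
#' One row per (target, factor) pair with shared up/down counts and the
#' comma-joined shared genes — the tabular companion of the diseasome
#' networks.
#'
#' @param target `DEGSet` of the target condition.
#' @param factors list of factor `DEGSet`s.
#' @param direction_consistent passed to [intersect_pair()].
#' @return data.frame with columns target, factor, n_up, n_down, n_shared,
#'   genes.
#' @export
pairwise_summary <- function(target, factors, direction_consistent = TRUE) {
  rows <- lapply(factors, function(f) {
    p <- intersect_pair(target, f, direction_consistent)
    data.frame(target = p$target_id, factor = p$factor_id,
               n_up = length(p$shared_up), n_down = length(p$shared_down),
               n_shared = p$n_shared,
               genes = paste(sort(c(p$shared_up, p$shared_down)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
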