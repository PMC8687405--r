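#' Simulate a family of case/control expression cohorts with planted DEGs
#'
#' Emulates the statistical structure a cross-condition DEG comparison
#' assumes: per condition, a genes x samples intensity matrix in which a
#' chosen set of genes is differentially expressed between case and control
#' with a fixed log2 effect size, and a designed amount of DEG sharing
#' between condition pairs. Log2 intensities are gene baselines (log2 of
#' lognormal raw baselines) plus i.i.d. Gaussian noise; planted DEGs shift
#' the case group by +/- `effect_size` log2 units. Matrices are returned on
#' the raw scale (`2^log2value`), as read from arrays.
#'
#' Pairwise sharing is realised with disjoint gene blocks: for every pair
#' (i, j) with a positive design entry, a dedicated block of genes is planted
#' (same direction) in exactly conditions i and j, so pairwise shared counts
#' equal the design exactly. Remaining per-condition DEG quota is filled with
#' condition-unique genes.
#'
#' @param n_conditions number of conditions; the first is the target.
#' @param n_genes genes per matrix (default 2000).
#' @param n_case,n_ctrl samples per group (default 10 each).
#' @param n_deg_per_condition planted DEGs per condition (scalar or vector of
#'   length `n_conditions`, default 50).
#' @param overlap_design symmetric `n_conditions` x `n_conditions` integer
#'   matrix; entry (i, j) is the number of DEGs planted jointly (same
#'   direction) in conditions i and j. Diagonal ignored. Default: no overlap.
#' @param effect_size planted |log2 fold change| (default 2.0).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.5).
#' @param baseline_meanlog,baseline_sdlog parameters of the lognormal raw
#'   baseline: log2 of the baseline intensity is N(meanlog2, sdlog2), default
#'   7 and 1 (typical array intensities of a few hundred units).
#' @param condition_ids labels; default `COND1`...
#' @param seed integer seed; same seed reproduces matrices bit-identically.
#' @return list with `matrices` (list of [ExpressionMatrix()], raw scale) and
#'   `truth` (class `SimulationTruth`): per-condition planted `up`/`down`
#'   sets, the `overlap_design`, per-pair planted shared gene blocks, all
#'   generator parameters and the seed.
#' @export
simulate_condition_family <- function(n_conditions = 2, n_genes = 2000,
                                      n_case = 10, n_ctrl = 10,
                                      n_deg_per_condition = 50,
                                      overlap_design = NULL,
                                      effect_size = 2.0, noise_sd = 0.5,
                                      baseline_meanlog = 7, baseline_sdlog = 1,
                                      condition_ids = paste0("COND", seq_len(n_conditions)),
                                      seed = 1L) {
  n_deg <- rep_len(n_deg_per_condition, n_conditions)
  if (is.null(overlap_design))
    overlap_design <- matrix(0L, n_conditions, n_conditions)
  overlap_design <- as.matrix(overlap_design)
  if (!all(dim(overlap_design) == n_conditions))
    stop("overlap_design must be ", n_conditions, " x ", n_conditions)
  if (!isTRUE(all.equal(overlap_design, t(overlap_design))))
    stop("overlap_design must be symmetric")
  diag(overlap_design) <- 0L
  committed <- rowSums(overlap_design)
  infeasible <- which(committed > n_deg)
  if (length(infeasible))
    stop("infeasible overlap design: condition ", condition_ids[infeasible[1]],
         " needs ", committed[infeasible[1]], " shared DEGs but has quota ",
         n_deg[infeasible[1]])
  genes <- sprintf("G%05d", seq_len(n_genes))
  if (sum(overlap_design[upper.tri(overlap_design)]) +
      sum(n_deg - committed) > n_genes)
    stop("not enough genes for the requested DEG plan")

  set.seed(seed)
  # allocate disjoint blocks: pair blocks first, then unique fillers
  pool <- sample(genes)   # randomise which symbols are planted
  take <- function(n) {
    if (n == 0) return(character(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  planted_up <- planted_down <- rep(list(character(0)), n_conditions)
  pair_blocks <- list()
  for (i in seq_len(n_conditions)) for (j in seq_len(n_conditions)) {
    if (j <= i || overlap_design[i, j] == 0) next
    block <- take(overlap_design[i, j])
    dirs <- sample(c("up", "down"), length(block), replace = TRUE)
    for (cond in c(i, j)) {
      planted_up[[cond]] <- c(planted_up[[cond]], block[dirs == "up"])
      planted_down[[cond]] <- c(planted_down[[cond]], block[dirs == "down"])
    }
    pair_blocks[[paste(condition_ids[i], condition_ids[j], sep = "~")]] <-
      data.frame(gene = block, direction = dirs, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_conditions)) {
    extra <- take(n_deg[i] - committed[i])
    dirs <- sample(c("up", "down"), length(extra), replace = TRUE)
    planted_up[[i]] <- sort(c(planted_up[[i]], extra[dirs == "up"]))
    planted_down[[i]] <- sort(c(planted_down[[i]], extra[dirs == "down"]))
  }

  sample_ids <- function(prefix) c(paste0(prefix, "_case", seq_len(n_case)),
                                   paste0(prefix, "_ctrl", seq_len(n_ctrl)))
  matrices <- vector("list", n_conditions)
  for (i in seq_len(n_conditions)) {
    baseline <- stats::rnorm(n_genes, baseline_meanlog, baseline_sdlog)
    ids <- sample_ids(condition_ids[i])
    log2v <- matrix(stats::rnorm(n_genes * (n_case + n_ctrl), 0, noise_sd),
                    n_genes, n_case + n_ctrl) + baseline
    case_cols <- seq_len(n_case)
    up_idx <- match(planted_up[[i]], genes)
    down_idx <- match(planted_down[[i]], genes)
    log2v[up_idx, case_cols] <- log2v[up_idx, case_cols] + effect_size
    log2v[down_idx, case_cols] <- log2v[down_idx, case_cols] - effect_size
    raw <- 2^log2v
    dimnames(raw) <- list(genes, ids)
    groups <- stats::setNames(c(rep("case", n_case), rep("control", n_ctrl)), ids)
    matrices[[i]] <- ExpressionMatrix(raw, groups = groups,
                                      condition_id = condition_ids[i],
                                      gene_ids = genes, scale = "raw")
  }
  names(matrices) <- condition_ids
  truth <- structure(
    list(condition_ids = condition_ids,
         up = stats::setNames(planted_up, condition_ids),
         down = stats::setNames(planted_down, condition_ids),
         overlap_design = overlap_design,
         pair_blocks = pair_blocks,
         params = list(n_conditions = n_conditions, n_genes = n_genes,
                       n_case = n_case, n_ctrl = n_ctrl,
                       n_deg_per_condition = n_deg,
                       effect_size = effect_size, noise_sd = noise_sd,
                       baseline_meanlog = baseline_meanlog,
                       baseline_sdlog = baseline_sdlog),
         seed = seed),
    class = "SimulationTruth")
  list(matrices = matrices, truth = truth)
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf("SimulationTruth: %d conditions, %d genes, seed %d\n",
              length(x$condition_ids), x$params$n_genes, x$seed))
  for (id in x$condition_ids)
    cat(sprintf("  %s: %d up, %d down planted\n", id,
                length(x$up[[id]]), length(x$down[[id]])))
  invisible(x)
}

#' Planted DEG sets of a SimulationTruth as DEGSets
#' @param truth a `SimulationTruth`.
#' @return named list of [deg_set()] objects, one per condition.
#' @export
truth_deg_sets <- function(truth) {
  stats::setNames(lapply(truth$condition_ids, function(id)
    deg_set(id, truth$up[[id]], truth$down[[id]])), truth$condition_ids)
}

#' Simulate a scale-free-style PPI network with planted hubs
#'
#' Grows an undirected preferential-attachment graph over the supplied gene
#' symbols (heavy-tailed degrees, as in protein interactomes), then wires
#' each planted hub to `planted_hub_degree` distinct partners so it dominates
#' the degree ranking. No self-loops; single connected component.
#'
#' @param genes character vector of node symbols (length >= 3).
#' @param attachment_m edges added per new node (default 2).
#' @param planted_hubs symbols (subset of `genes`) to boost; default none.
#' @param planted_hub_degree guaranteed minimum degree of each planted hub
#'   (default 30).
#' @param weight_range range of uniform edge confidences (default c(0.4, 1)).
#' @param seed integer seed.
#' @return An [InteractionNetwork()] of kind `ppi_undirected`.
#' @export
simulate_ppi <- function(genes, attachment_m = 2, planted_hubs = character(0),
                         planted_hub_degree = 30, weight_range = c(0.4, 1),
                         seed = 1L) {
  genes <- unique(toupper(genes))
  n <- length(genes)
  if (n < 3) stop("need at least 3 genes")
  if (length(setdiff(toupper(planted_hubs), genes)))
    stop("planted hubs must be a subset of genes")
  set.seed(seed)
  g <- igraph::sample_pa(n, m = attachment_m, directed = FALSE)
  perm <- sample(n)   # detach symbol order from attachment order
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = genes[perm[el[, 1]]], to = genes[perm[el[, 2]]],
                      stringsAsFactors = FALSE)
  for (hub in toupper(planted_hubs)) {
    partners <- sample(setdiff(genes, hub), planted_hub_degree)
    edges <- rbind(edges, data.frame(from = hub, to = partners,
                                     stringsAsFactors = FALSE))
  }
  edges$weight <- round(stats::runif(nrow(edges), weight_range[1], weight_range[2]), 3)
  nodes <- data.frame(id = sort(genes), class = "protein",
                      stringsAsFactors = FALSE)
  InteractionNetwork(edges, kind = "ppi_undirected", nodes = nodes)
}

#' Simulate a gene-set library with one planted enriched term
#'
#' Random GMT-style library over a gene universe, with one designated term
#' composed of planted genes (e.g. the planted DEGs) so that a query drawn
#' largely from those genes is enriched for it; all other terms are uniform
#' random draws from the universe.
#'
#' @param universe character vector of all genes.
#' @param n_terms number of terms (default 50).
#' @param term_size_range integer range of random term sizes (default
#'   c(10, 40)).
#' @param planted_genes genes forming the planted term (subset of universe).
#' @param planted_term_id id of the planted term (default `"TERM_PLANTED"`).
#' @param seed integer seed.
#' @return A [GeneSetLibrary()] with universe = `universe`.
#' @export
simulate_gmt <- function(universe, n_terms = 50, term_size_range = c(10, 40),
                         planted_genes = character(0),
                         planted_term_id = "TERM_PLANTED", seed = 1L) {
  universe <- unique(toupper(universe))
  planted_genes <- unique(toupper(planted_genes))
  if (length(setdiff(planted_genes, universe)))
    stop("planted genes must be in the universe")
  set.seed(seed)
  sets <- list()
  for (i in seq_len(n_terms)) {
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    sets[[sprintf("TERM_%03d", i)]] <-
      list(description = sprintf("random term %d", i),
           genes = sample(universe, size))
  }
  if (length(planted_genes))
    sets[[planted_term_id]] <- list(description = "planted enriched term",
                                    genes = planted_genes)
  GeneSetLibrary(sets, name = "synthetic", universe = universe)
}

#' Simulate a regulator->target table with one boosted regulator
#'
#' Random bipartite regulator->gene edges; the planted regulator's target set
#' is drawn preferentially from the supplied DEGs so it tops a
#' DEG-restricted degree ranking.
#'
#' @param universe character vector of candidate target genes.
#' @param degs planted DEG symbols the boosted regulator should target.
#' @param n_regulators number of regulators (default 20).
#' @param targets_per_regulator targets per random regulator (default 15).
#' @param planted_regulator id of the boosted regulator (default
#'   `"TF_PLANTED"`); `NULL` for none.
#' @param planted_deg_targets number of distinct DEGs the planted regulator
#'   targets (default `min(10, length(degs))`).
#' @param regulator_prefix id prefix for random regulators (default `"TF"`).
#' @param seed integer seed.
#' @return An [InteractionNetwork()] of kind `regulator_bipartite`.
#' @export
simulate_regulator_tables <- function(universe, degs, n_regulators = 20,
                                      targets_per_regulator = 15,
                                      planted_regulator = "TF_PLANTED",
                                      planted_deg_targets = min(10, length(degs)),
                                      regulator_prefix = "TF", seed = 1L) {
  universe <- unique(toupper(universe))
  degs <- intersect(unique(toupper(degs)), universe)
  set.seed(seed)
  edges <- list()
  for (i in seq_len(n_regulators)) {
    reg <- sprintf("%s_%03d", regulator_prefix, i)
    edges[[reg]] <- data.frame(from = reg,
                               to = sample(universe, targets_per_regulator),
                               stringsAsFactors = FALSE)
  }
  if (!is.null(planted_regulator)) {
    if (planted_deg_targets > length(degs))
      stop("planted_deg_targets exceeds available DEGs")
    tgt <- c(sample(degs, planted_deg_targets),
             sample(setdiff(universe, degs), 5))
    edges[[planted_regulator]] <- data.frame(from = planted_regulator, to = tgt,
                                             stringsAsFactors = FALSE)
  }
  InteractionNetwork(do.call(rbind, edges), kind = "regulator_bipartite")
}

#' Simulate a drug->target table
#'
#' Random drug->gene edges plus designated drugs wired to specific query
#' genes, mirroring curated drug-target databases.
#'
#' @param universe candidate target genes.
#' @param target_genes genes the planted drugs must hit.
#' @param n_drugs number of random drugs (default 15).
#' @param targets_per_drug targets per random drug (default 4).
#' @param n_planted_drugs drugs guaranteed to hit `target_genes` (default 3).
#' @param seed integer seed.
#' @return An [InteractionNetwork()] of kind `drug_bipartite`.
#' @export
simulate_drug_tables <- function(universe, target_genes = character(0),
                                 n_drugs = 15, targets_per_drug = 4,
                                 n_planted_drugs = 3, seed = 1L) {
  universe <- unique(toupper(universe))
  target_genes <- intersect(unique(toupper(target_genes)), universe)
  set.seed(seed)
  edges <- list()
  for (i in seq_len(n_drugs)) {
    d <- sprintf("DRUG_%03d", i)
    edges[[d]] <- data.frame(from = d, to = sample(universe, targets_per_drug),
                             stringsAsFactors = FALSE)
  }
  if (length(target_genes) && n_planted_drugs > 0) {
    for (i in seq_len(n_planted_drugs)) {
      d <- sprintf("DRUG_PLANTED_%02d", i)
      edges[[d]] <- data.frame(
        from = d,
        to = sample(target_genes, min(targets_per_drug, length(target_genes))),
        stringsAsFactors = FALSE)
    }
  }
  InteractionNetwork(do.call(rbind, edges), kind = "drug_bipartite")
}

#' Simulate a disease gene list overlapping a DEG set
#'
#' Curated-list stand-in: a mix of planted DEGs and random background genes,
#' so that gene-disease association tests have signal.
#'
#' @param universe all genes.
#' @param degs DEG symbols to seed the list with.
#' @param n_from_degs DEGs included (default `min(10, length(degs))`).
#' @param n_background random non-DEG genes included (default 20).
#' @param seed integer seed.
#' @return sorted character vector of disease genes.
#' @export
simulate_disease_genes <- function(universe, degs, n_from_degs = min(10, length(degs)),
                                   n_background = 20, seed = 1L) {
  universe <- unique(toupper(universe))
  degs <- intersect(unique(toupper(degs)), universe)
  set.seed(seed)
  sort(c(sample(degs, n_from_degs),
         sample(setdiff(universe, degs), n_background)))
}
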