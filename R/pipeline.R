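#' Write a self-contained synthetic analysis workspace
#'
#' Generates every input the pipeline consumes — per-condition expression
#' matrices with group maps, a gene-set library (GMT), a PPI edge list, TF and
#' miRNA regulator tables, a drug-target table, a disease gene list — plus a
#' ground-truth manifest (JSON) and a ready-to-run pipeline config (YAML).
#' The planted structure ties everything together: shared planted DEGs feed
#' the planted enriched term, the planted PPI hub, the boosted regulators and
#' the disease list, so end-to-end recovery can be asserted against truth.
#'
#' @param dir output directory (created if needed).
#' @param n_conditions,n_genes,n_case,n_ctrl,n_deg_per_condition,overlap_design,effect_size,noise_sd
#'   passed to [simulate_condition_family()].
#' @param seed master integer seed; all component seeds derive from it.
#' @return the config file path, invisibly; the truth manifest is at
#'   `truth.json` in `dir`.
#' @export
simulate_workspace <- function(dir, n_conditions = 5, n_genes = 1200,
                               n_case = 10, n_ctrl = 10,
                               n_deg_per_condition = 40,
                               overlap_design = NULL,
                               effect_size = 2.0, noise_sd = 0.5,
                               seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(overlap_design)) {
    # default: target (condition 1) shares a planted block with every factor
    overlap_design <- matrix(0L, n_conditions, n_conditions)
    if (n_conditions > 1) {
      overlap_design[1, -1] <- 10L
      overlap_design[-1, 1] <- 10L
    }
  }
  condition_ids <- c("TARGET", if (n_conditions > 1)
    paste0("RF", seq_len(n_conditions - 1)))
  fam <- simulate_condition_family(
    n_conditions = n_conditions, n_genes = n_genes, n_case = n_case,
    n_ctrl = n_ctrl, n_deg_per_condition = n_deg_per_condition,
    overlap_design = overlap_design, effect_size = effect_size,
    noise_sd = noise_sd, condition_ids = condition_ids, seed = seed)
  truth <- fam$truth

  conds <- list()
  for (id in condition_ids) {
    m <- fam$matrices[[id]]
    expr_path <- file.path(dir, paste0(id, "_expression.tsv"))
    grp_path <- file.path(dir, paste0(id, "_groups.tsv"))
    write_expression(m, expr_path)
    utils::write.table(data.frame(sample = names(m$groups),
                                  group = unname(m$groups)),
                       grp_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    conds[[id]] <- list(id = id, expression = basename(expr_path),
                        groups = basename(grp_path))
  }

  genes <- fam$matrices[[1]]$gene_ids
  shared <- sort(unique(unlist(lapply(truth$pair_blocks, `[[`, "gene"))))
  target_degs <- sort(c(truth$up[["TARGET"]], truth$down[["TARGET"]]))
  anchor <- if (length(shared)) shared else target_degs

  ppi <- simulate_ppi(genes, planted_hubs = anchor[1],
                      planted_hub_degree = 30, seed = seed + 1L)
  write_network(ppi, file.path(dir, "ppi.tsv"), format = "tsv")

  lib <- simulate_gmt(genes, n_terms = 40, planted_genes = anchor,
                      seed = seed + 2L)
  write_gmt(lib, file.path(dir, "genesets.gmt"))

  tf <- simulate_regulator_tables(genes, anchor, planted_regulator = "TF_PLANTED",
                                  regulator_prefix = "TF", seed = seed + 3L)
  write_network(tf, file.path(dir, "tf_targets.tsv"), format = "tsv")
  mir <- simulate_regulator_tables(genes, anchor,
                                   planted_regulator = "MIR_PLANTED",
                                   regulator_prefix = "MIR", seed = seed + 4L)
  write_network(mir, file.path(dir, "mirna_targets.tsv"), format = "tsv")

  drugs <- simulate_drug_tables(genes, anchor, seed = seed + 5L)
  write_network(drugs, file.path(dir, "drug_targets.tsv"), format = "tsv")

  disease <- simulate_disease_genes(genes, target_degs, seed = seed + 6L)
  writeLines(disease, file.path(dir, "disease_genes.txt"))

  truth_json <- list(
    condition_ids = truth$condition_ids,
    up = truth$up, down = truth$down,
    overlap_design = truth$overlap_design,
    pair_blocks = lapply(truth$pair_blocks, function(b) as.list(b)),
    planted_hub = anchor[1],
    planted_term = "TERM_PLANTED",
    planted_tf = "TF_PLANTED", planted_mirna = "MIR_PLANTED",
    params = truth$params, seed = truth$seed)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  config <- list(
    target = conds[[1]],
    factors = unname(conds[-1]),
    alpha = 0.05, lfc = 1.0, log2_offset = 1.0,
    collapse_method = "max_abs_t",
    direction_consistent = TRUE, neighbor_expansion = FALSE,
    ppi = list(path = "ppi.tsv", weight_threshold = 0.4),
    gene_sets = "genesets.gmt",
    tf_targets = "tf_targets.tsv",
    mirna_targets = "mirna_targets.tsv",
    drug_targets = "drug_targets.tsv",
    disease_genes = "disease_genes.txt",
    n_hubs = 10, n_regulators = 5,
    seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

read_gene_list <- function(path) {
  x <- readLines(path)
  sort(unique(toupper(x[nzchar(x)])))
}

resolve_path <- function(p, base) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(base, p)
}

validate_config <- function(cfg, base) {
  need <- function(p, what) {
    rp <- resolve_path(p, base)
    if (is.null(rp) || !file.exists(rp))
      stop("config validation: missing ", what, " file: ", p)
    rp
  }
  cfg$target$expression <- need(cfg$target$expression, "target expression")
  cfg$target$groups <- need(cfg$target$groups, "target groups")
  for (i in seq_along(cfg$factors)) {
    cfg$factors[[i]]$expression <- need(cfg$factors[[i]]$expression,
                                        paste0("factor ", i, " expression"))
    cfg$factors[[i]]$groups <- need(cfg$factors[[i]]$groups,
                                    paste0("factor ", i, " groups"))
  }
  cfg$ppi$path <- need(cfg$ppi$path, "PPI")
  cfg$gene_sets <- need(cfg$gene_sets, "gene sets")
  cfg$tf_targets <- need(cfg$tf_targets, "TF targets")
  cfg$mirna_targets <- need(cfg$mirna_targets, "miRNA targets")
  cfg$drug_targets <- need(cfg$drug_targets, "drug targets")
  cfg$disease_genes <- need(cfg$disease_genes, "disease genes")
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (is.null(cfg$lfc)) cfg$lfc <- 1.0
  if (cfg$alpha <= 0 || cfg$lfc < 0) stop("thresholds must be positive")
  if (is.null(cfg$log2_offset)) cfg$log2_offset <- 1.0
  if (is.null(cfg$collapse_method)) cfg$collapse_method <- "max_abs_t"
  if (is.null(cfg$direction_consistent)) cfg$direction_consistent <- TRUE
  if (is.null(cfg$neighbor_expansion)) cfg$neighbor_expansion <- FALSE
  if (is.null(cfg$n_hubs)) cfg$n_hubs <- 10
  if (is.null(cfg$n_regulators)) cfg$n_regulators <- 5
  cfg
}

#' Run the full diseasome analysis pipeline
#'
#' Orchestrates every stage from a declarative config: per-condition
#' preprocessing (log2, probe collapsing) and DEG calling; up/down diseasome
#' networks and pairwise/multiway shared-gene reports; over-representation of
#' the shared genes in the gene-set library; PPI subnetwork induction and hub
#' ranking; TF and miRNA regulator ranking; drug-target lookup; and
#' gene-disease association of each condition's DEGs against the disease
#' list, BH-corrected across conditions. Every intermediate artifact is
#' written to `out_dir`, and a manifest (parameters, counts, md5 hashes of
#' all outputs) makes reruns byte-comparable: identical config and inputs
#' give identical manifests.
#'
#' @param config a config list or path to a YAML config (as written by
#'   [simulate_workspace()]). Relative paths are resolved against the config
#'   file's directory.
#' @param out_dir output directory (default `<config dir>/results`).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config, base)
  if (is.null(out_dir)) out_dir <- file.path(base, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    outputs <<- c(outputs, p)
    p
  }

  # --- preprocess + DEG per condition ------------------------------------
  all_conds <- c(list(cfg$target), cfg$factors)
  degsets <- list()
  measured <- character(0)
  for (cond in all_conds) {
    m <- read_expression(cond$expression, cond$groups, condition_id = cond$id)
    m <- log2_transform(m, offset = cfg$log2_offset)
    m <- collapse_probes(m, method = cfg$collapse_method)
    measured <- union(measured, m$gene_ids)
    ds <- call_degs(m, alpha = cfg$alpha, lfc = cfg$lfc)
    write_deg_table(ds, emit(paste0("deg_", cond$id, ".tsv")))
    degsets[[cond$id]] <- ds
  }
  target <- degsets[[cfg$target$id]]
  factors <- degsets[names(degsets) != cfg$target$id]

  # --- diseasome ---------------------------------------------------------
  pw <- pairwise_summary(target, factors, cfg$direction_consistent)
  utils::write.table(pw, emit("pairwise_shared.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  net_up <- suppressWarnings(build_diseasome(target, factors, "up",
                                             cfg$direction_consistent))
  net_down <- suppressWarnings(build_diseasome(target, factors, "down",
                                               cfg$direction_consistent))
  write_network(net_up, emit("diseasome_up.tsv"), format = "tsv")
  write_network(net_down, emit("diseasome_down.tsv"), format = "tsv")
  write_network(net_up, emit("diseasome_up.sif"), format = "sif")
  write_network(net_down, emit("diseasome_down.sif"), format = "sif")
  mw <- multiway_shared(degsets, min_conditions = 2L)
  utils::write.table(mw, emit("multiway_shared.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  shared_genes <- sort(union(
    net_up$nodes$id[net_up$nodes$class == "gene"],
    net_down$nodes$id[net_down$nodes$class == "gene"]))

  # --- enrichment of the shared genes ------------------------------------
  lib <- read_gmt(cfg$gene_sets)
  enrich_universe <- intersect(lib$universe, measured)
  enr <- if (length(shared_genes) && length(intersect(shared_genes, enrich_universe))) {
    enrich(shared_genes, lib, universe = enrich_universe)
  } else {
    data.frame()
  }
  utils::write.table(enr, emit("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- PPI hubs ----------------------------------------------------------
  ppi <- read_edge_list(cfg$ppi$path, kind = "ppi_undirected",
                        weight_threshold = cfg$ppi$weight_threshold)
  sub <- induce_subnetwork(ppi, shared_genes,
                           expand_neighbors = cfg$neighbor_expansion)
  write_network(sub, emit("ppi_subnetwork.tsv"), format = "tsv")
  hubs <- if (n_nodes(sub) > 0) rank_hubs(sub, k = cfg$n_hubs) else data.frame()
  utils::write.table(hubs, emit("hubs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- regulators and drugs ----------------------------------------------
  tf_net <- read_edge_list(cfg$tf_targets, kind = "regulator_bipartite")
  mir_net <- read_edge_list(cfg$mirna_targets, kind = "regulator_bipartite")
  tf_rank <- suppressWarnings(rank_regulators(tf_net, shared_genes,
                                              top_n = cfg$n_regulators,
                                              regulator_class = "TF"))
  mir_rank <- suppressWarnings(rank_regulators(mir_net, shared_genes,
                                               top_n = cfg$n_regulators,
                                               regulator_class = "miRNA"))
  utils::write.table(tf_rank, emit("tf_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mir_rank, emit("mirna_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  drug_net <- read_edge_list(cfg$drug_targets, kind = "drug_bipartite")
  drug_sub <- drug_interactions(drug_net, shared_genes)
  write_network(drug_sub, emit("drug_interactions.tsv"), format = "tsv")

  # --- gene-disease association ------------------------------------------
  disease <- read_gene_list(cfg$disease_genes)
  assoc <- do.call(rbind, lapply(names(degsets), function(id) {
    r <- suppressMessages(gene_disease_association(deg_genes(degsets[[id]]),
                                                   disease, measured))
    cbind(condition = id, r, stringsAsFactors = FALSE)
  }))
  assoc$p_adj <- benjamini_hochberg(assoc$p)
  utils::write.table(assoc, emit("gene_disease_association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- manifest ----------------------------------------------------------
  outputs <- sort(outputs)
  hashes <- as.list(tools::md5sum(outputs))
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    parameters = list(alpha = cfg$alpha, lfc = cfg$lfc,
                      log2_offset = cfg$log2_offset,
                      collapse_method = cfg$collapse_method,
                      direction_consistent = cfg$direction_consistent,
                      neighbor_expansion = cfg$neighbor_expansion,
                      ppi_weight_threshold = cfg$ppi$weight_threshold,
                      n_hubs = cfg$n_hubs, n_regulators = cfg$n_regulators,
                      seed = cfg$seed,
                      enrichment_universe = "library universe intersected with measured genes"),
    counts = list(
      conditions = length(degsets),
      degs_per_condition = lapply(degsets, function(d)
        list(up = length(d$up), down = length(d$down))),
      shared_genes = length(shared_genes),
      diseasome_up_edges = n_edges(net_up),
      diseasome_down_edges = n_edges(net_down),
      enriched_terms_p_adj_lt_alpha = if (nrow(enr)) sum(enr$p_adj < cfg$alpha) else 0L,
      ppi_subnetwork_edges = n_edges(sub),
      drugs_linked = if (n_edges(drug_sub)) length(unique(drug_sub$edges$from)) else 0L),
    files = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
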