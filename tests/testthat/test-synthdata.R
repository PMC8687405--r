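test_that("simulated cohorts are reproducible and honour the planted design", {
  design <- matrix(c(0L, 10L, 10L, 0L), 2, 2)
  a <- simulate_condition_family(n_conditions = 2, n_genes = 300,
                                 n_deg_per_condition = 20,
                                 overlap_design = design, seed = 99)
  b <- simulate_condition_family(n_conditions = 2, n_genes = 300,
                                 n_deg_per_condition = 20,
                                 overlap_design = design, seed = 99)
  expect_identical(a$matrices[[1]]$values, b$matrices[[1]]$values)
  expect_identical(a$truth$up, b$truth$up)

  truth <- a$truth
  for (i in 1:2)
    expect_equal(length(truth$up[[i]]) + length(truth$down[[i]]), 20L)
  shared <- intersect(c(truth$up[[1]], truth$down[[1]]),
                      c(truth$up[[2]], truth$down[[2]]))
  expect_equal(length(shared), 10L)
  # shared genes carry the same direction in both conditions
  expect_setequal(intersect(truth$up[[1]], shared),
                  intersect(truth$up[[2]], shared))
})

test_that("infeasible overlap designs are rejected with the offending cell", {
  design <- matrix(c(0L, 30L, 30L, 0L), 2, 2)
  expect_error(simulate_condition_family(n_conditions = 2,
                                         n_deg_per_condition = 20,
                                         overlap_design = design),
               "infeasible")
  asym <- matrix(c(0L, 3L, 5L, 0L), 2, 2)
  expect_error(simulate_condition_family(n_conditions = 2,
                                         overlap_design = asym), "symmetric")
})

test_that("strong planted effects are recovered end-to-end by DEG calling", {
  design <- matrix(c(0L, 10L, 10L, 0L), 2, 2)
  fam <- simulate_condition_family(n_conditions = 2, n_genes = 500,
                                   n_deg_per_condition = 25,
                                   overlap_design = design,
                                   effect_size = 3, noise_sd = 0.3, seed = 7)
  called <- lapply(fam$matrices, function(m)
    call_degs(collapse_probes(log2_transform(m), method = "mean")))
  pair <- intersect_pair(called[[1]], called[[2]])
  expect_gte(pair$n_shared, 9L)

  # null generator: no effect, essentially nothing significant
  null_fam <- simulate_condition_family(n_conditions = 1, n_genes = 500,
                                        n_deg_per_condition = 0,
                                        effect_size = 0, seed = 8)
  null_called <- call_degs(collapse_probes(log2_transform(null_fam$matrices[[1]]),
                                           method = "mean"))
  expect_lte(length(deg_genes(null_called)), 500 * 0.05)
})

test_that("simulated matrices round-trip through the readers unchanged", {
  fam <- simulate_condition_family(n_conditions = 1, n_genes = 40,
                                   n_case = 3, n_ctrl = 3,
                                   n_deg_per_condition = 5, seed = 12)
  m <- fam$matrices[[1]]
  dir <- tempfile(); dir.create(dir)
  expr <- file.path(dir, "e.tsv"); grp <- file.path(dir, "g.tsv")
  write_expression(m, expr)
  write.table(data.frame(names(m$groups), unname(m$groups)), grp,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  back <- read_expression(expr, grp, condition_id = m$condition_id)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  expect_equal(back$groups[colnames(back$values)],
               m$groups[colnames(m$values)])
})

test_that("simulated PPI graphs have planted hubs on top and no self-loops", {
  genes <- sprintf("P%03d", 1:150)
  net <- simulate_ppi(genes, planted_hubs = "P007", planted_hub_degree = 40,
                      seed = 2)
  expect_true(all(net$edges$from != net$edges$to))
  expect_true(all(net$edges$weight >= 0 & net$edges$weight <= 1))
  expect_gte(unname(node_degrees(net)["P007"]), 40L)
  expect_equal(rank_hubs(net, k = 1)$node[1], "P007")
  expect_true(igraph::is_connected(
    igraph::graph_from_data_frame(net$edges, directed = FALSE)))

  net2 <- simulate_ppi(genes, planted_hubs = "P007", planted_hub_degree = 40,
                       seed = 2)
  expect_identical(net2$edges, net$edges)
})

test_that("simulated libraries cover the universe and plant one enriched term", {
  universe <- sprintf("G%04d", 1:300)
  planted <- sample(universe, 20)
  lib <- simulate_gmt(universe, n_terms = 25, planted_genes = planted, seed = 3)
  expect_equal(lib$universe, sort(universe))
  expect_setequal(lib$sets$TERM_PLANTED$genes, toupper(planted))
  lib2 <- simulate_gmt(universe, n_terms = 25, planted_genes = planted, seed = 3)
  expect_identical(lib2$sets, lib$sets)
})

test_that("planted regulators rank first against their DEGs", {
  universe <- sprintf("G%04d", 1:300)
  for (s in 1:5) {
    set.seed(s)
    degs <- sample(universe, 30)
    net <- simulate_regulator_tables(universe, degs, n_regulators = 15,
                                     targets_per_regulator = 8, seed = s + 50)
    r <- rank_regulators(net, degs, top_n = 5)
    expect_equal(r$regulator[1], "TF_PLANTED")
  }
  net <- simulate_regulator_tables(universe, sample(universe, 10), seed = 1)
  expect_warning(rank_regulators(net, character(0)), "no regulator")
})
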