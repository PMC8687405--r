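test_that("intersect_pair honours direction consistency", {
  t_set <- deg_set("CMP", up = c("A", "B", "C"), down = c("X", "Y"))
  f_set <- deg_set("AG", up = c("B", "C", "D"), down = c("Y", "Z", "A2"))
  p <- intersect_pair(t_set, f_set)
  expect_equal(p$shared_up, c("B", "C"))
  expect_equal(p$shared_down, "Y")
  expect_equal(p$n_shared, 3L)

  # opposite direction blocks sharing under consistency, not without
  g1 <- deg_set("T", up = "G", down = character(0))
  g2 <- deg_set("F", up = character(0), down = "G")
  expect_equal(intersect_pair(g1, g2)$n_shared, 0L)
  loose <- intersect_pair(g1, g2, direction_consistent = FALSE)
  expect_equal(loose$shared_up, "G")

  mismatched <- deg_set("F2", up = "A", down = character(0),
                        thresholds = c(alpha = 0.01, lfc = 1.5))
  expect_warning(intersect_pair(t_set, mismatched), "thresholds")
})

test_that("pairwise shared counts match a brute-force set scan and are symmetric", {
  set.seed(12)
  pool <- sprintf("G%03d", 1:60)
  sets <- lapply(1:20, function(i) random_deg_set(paste0("C", i), pool))
  for (i in 1:10) {
    a <- sets[[sample(20, 1)]]; b <- sets[[sample(20, 1)]]
    p <- intersect_pair(a, b)
    brute <- length(intersect(a$up, b$up)) + length(intersect(a$down, b$down))
    expect_equal(p$n_shared, brute)
    expect_equal(intersect_pair(b, a)$n_shared, p$n_shared)
  }
})

test_that("build_diseasome matches hand enumeration", {
  t_set <- deg_set("CMP", up = c("B", "C", "Q"), down = "D1")
  f_set <- deg_set("AG", up = c("B", "C", "Z"), down = "D2")
  net <- build_diseasome(t_set, list(f_set), direction = "up")
  expect_equal(sum(net$nodes$class == "condition"), 2L)
  expect_equal(sort(net$nodes$id[net$nodes$class == "gene"]), c("B", "C"))
  expect_equal(n_edges(net), 4L)   # CMP-B, CMP-C, AG-B, AG-C

  expect_warning(
    empty <- build_diseasome(t_set, list(deg_set("SM", up = "W", down = "V"))),
    "no shared")
  expect_equal(sum(empty$nodes$class == "gene"), 0L)
  expect_equal(sum(empty$nodes$class == "condition"), 2L)
  expect_equal(n_edges(empty), 0L)
})

test_that("a planted overlap design is recovered exactly in the diseasome", {
  design <- matrix(0L, 3, 3)
  design[1, 2] <- design[2, 1] <- 6L
  design[1, 3] <- design[3, 1] <- 4L
  fam <- simulate_condition_family(n_conditions = 3, n_genes = 400,
                                   n_deg_per_condition = 15,
                                   overlap_design = design,
                                   effect_size = 4, noise_sd = 0.3, seed = 5)
  truth_sets <- truth_deg_sets(fam$truth)
  target <- truth_sets[[1]]

  for (j in 2:3) {
    p <- intersect_pair(target, truth_sets[[j]])
    expect_equal(p$n_shared, design[1, j])
  }
  up_net <- suppressWarnings(build_diseasome(target, truth_sets[-1], "up"))
  down_net <- suppressWarnings(build_diseasome(target, truth_sets[-1], "down"))
  # adjacency equals the planted block structure
  blocks <- fam$truth$pair_blocks
  for (nm in names(blocks)) {
    ids <- strsplit(nm, "~")[[1]]
    for (r in seq_len(nrow(blocks[[nm]]))) {
      g <- blocks[[nm]]$gene[r]
      net <- if (blocks[[nm]]$direction[r] == "up") up_net else down_net
      hit <- net$edges$to == g
      expect_setequal(net$edges$from[hit], ids)
    }
  }
  # union of up- and down-network gene nodes is the pairwise shared union
  gene_nodes <- union(up_net$nodes$id[up_net$nodes$class == "gene"],
                      down_net$nodes$id[down_net$nodes$class == "gene"])
  pair_union <- unique(unlist(lapply(truth_sets[-1], function(f) {
    p <- intersect_pair(target, f)
    c(p$shared_up, p$shared_down)
  })))
  expect_setequal(gene_nodes, pair_union)
})

test_that("multiway_shared tallies condition multiplicity correctly", {
  sets <- list(deg_set("C1", up = c("G", "H"), down = character(0)),
               deg_set("C2", up = "G", down = "K"),
               deg_set("C3", up = character(0), down = "G"),
               deg_set("C4", up = "G", down = "H"),
               deg_set("C5", up = "Z", down = character(0)))
  rep4 <- multiway_shared(sets, min_conditions = 4)
  expect_equal(rep4$gene, "G")
  expect_equal(rep4$n_conditions, 4L)
  expect_equal(rep4$conditions, "C1,C2,C3,C4")

  expect_equal(nrow(multiway_shared(sets, min_conditions = 5)), 0L)
  expect_error(multiway_shared(sets, min_conditions = 1), "at least 2")
  expect_error(multiway_shared(sets[1], min_conditions = 2), "at least 2")

  # random sets vs brute-force tally
  set.seed(8)
  pool <- sprintf("G%02d", 1:30)
  rsets <- lapply(1:6, function(i) random_deg_set(paste0("R", i), pool,
                                                  n_up = 5, n_down = 5))
  rep2 <- multiway_shared(rsets, min_conditions = 2)
  tally <- table(unlist(lapply(rsets, deg_genes)))
  expect_setequal(rep2$gene, names(tally)[tally >= 2])
  expect_equal(rep2$n_conditions,
               unname(as.integer(tally[rep2$gene])))
})

test_that("pairwise_summary table mirrors intersect_pair", {
  t_set <- deg_set("CMP", up = c("A", "B"), down = "C")
  f1 <- deg_set("AG", up = "A", down = "C")
  f2 <- deg_set("SM", up = "B", down = character(0))
  tab <- pairwise_summary(t_set, list(f1, f2))
  expect_equal(tab$n_shared, c(2L, 1L))
  expect_equal(tab$genes, c("A,C", "B"))
})
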