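test_that("expression matrices round-trip through TSV with group map", {
  fx <- fixture_expression()
  m <- read_expression(fx$expression, fx$groups, condition_id = "CMP")
  expect_s3_class(m, "ExpressionMatrix")
  expect_equal(dim(m$values), c(3L, 4L))
  expect_equal(m$gene_ids, c("TP53", "BRCA1", "EGFR"))
  expect_equal(unname(m$groups[colnames(m$values)]),
               c("case", "case", "control", "control"))
  expect_equal(m$scale, "raw")
  expect_equal(unname(m$values), unname(fx$values))

  out <- tempfile(fileext = ".tsv")
  write_expression(m, out)
  m2 <- read_expression(out, fx$groups, condition_id = "CMP")
  expect_equal(m2$values, m$values)
})

test_that("read_expression rejects bad input, naming the offender", {
  fx <- fixture_expression(groups = c(S1 = "case", S2 = "case", S4 = "control"))
  expect_error(read_expression(fx$expression, fx$groups), "S3")

  bad <- write_tsv_lines(c("gene\tS1\tS2\tS3\tS4",
                           "TP53\t1\t2\tx\t4"))
  fx2 <- fixture_expression()
  expect_error(read_expression(bad, fx2$groups), "TP53.*S3")

  empty <- write_tsv_lines(character(0))
  expect_error(read_expression(empty, fx2$groups), "empty")

  dup_samples <- write_tsv_lines(c("gene\tS1\tS1", "TP53\t1\t2"))
  expect_error(read_expression(dup_samples, fx2$groups), "duplicate sample")
})

test_that("duplicate gene rows are retained under distinct keys for collapsing", {
  grp <- write_tsv_lines(c("S1\tcase", "S2\tcase", "S3\tcontrol", "S4\tcontrol"))
  expr <- write_tsv_lines(c("gene\tS1\tS2\tS3\tS4",
                            "TP53\t1\t2\t3\t4",
                            "tp53\t5\t6\t7\t8",
                            "EGFR\t9\t10\t11\t12"))
  m <- read_expression(expr, grp)
  expect_equal(nrow(m$values), 3L)
  expect_equal(m$gene_ids, c("TP53", "TP53", "EGFR"))
  expect_equal(anyDuplicated(rownames(m$values)), 0L)
  expect_equal(unname(m$values[2, ]), c(5, 6, 7, 8))
})

test_that("GMT files parse, validate and round-trip", {
  gmt <- write_tsv_lines(c("T1\tfirst\ta\tB",
                           "T2\tsecond\tb\tC"))
  lib <- read_gmt(gmt)
  expect_s3_class(lib, "GeneSetLibrary")
  expect_setequal(lib$universe, c("A", "B", "C"))
  expect_setequal(lib$sets$T1$genes, c("A", "B"))

  bad <- write_tsv_lines(c("T1\tdesc\tA", "T2\tdesc"))
  expect_error(read_gmt(bad), "line 2")

  out <- tempfile(fileext = ".gmt")
  write_gmt(lib, out)
  lib2 <- read_gmt(out)
  expect_equal(lib2$sets, lib$sets)
  expect_equal(lib2$universe, lib$universe)
})

test_that("edge lists canonicalize, deduplicate and drop self-loops", {
  path <- write_tsv_lines(c("A\tB\t0.9", "B\tA\t0.9", "C\tC\t0.5"))
  net <- suppressMessages(read_edge_list(path, "ppi_undirected",
                                         weight_threshold = NULL))
  expect_equal(n_edges(net), 1L)
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")
  expect_equal(net$n_self_loops_dropped, 1L)
})

test_that("weight threshold filters PPI edges; STRING scores are rescaled", {
  path <- write_tsv_lines(c("A\tB\t0.9", "C\tD\t0.5"))
  net <- read_edge_list(path, "ppi_undirected", weight_threshold = 0.7)
  expect_equal(n_edges(net), 1L)

  string <- write_tsv_lines(c("A\tB\t900", "C\tD\t350"))
  net2 <- suppressMessages(read_edge_list(string, "ppi_undirected",
                                          weight_threshold = 0.4))
  expect_equal(n_edges(net2), 1L)
  expect_equal(net2$edges$weight, 0.9)

  neg <- write_tsv_lines(c("A\tB\t-0.2"))
  expect_error(read_edge_list(neg, "ppi_undirected"), "\\[0, 1\\]")
})

test_that("threshold filtering matches a linear-scan count on a random fixture", {
  set.seed(11)
  n <- 100
  a <- sprintf("N%03d", sample(60, n, replace = TRUE))
  b <- sprintf("N%03d", sample(61:120, n, replace = TRUE))
  w <- round(runif(n), 3)
  path <- write_tsv_lines(paste(a, b, w, sep = "\t"))
  for (t in c(0.2, 0.5, 0.8)) {
    net <- read_edge_list(path, "ppi_undirected", weight_threshold = t)
    # oracle: scan raw triples, canonicalize by hand, deduplicate
    keep <- w >= t
    key <- ifelse(a[keep] < b[keep], paste(a[keep], b[keep]),
                  paste(b[keep], a[keep]))
    expect_equal(n_edges(net), length(unique(key)))
  }
})

test_that("network writers round-trip and canonicalization is idempotent", {
  set.seed(3)
  edges <- data.frame(from = sample(LETTERS[1:8], 15, replace = TRUE),
                      to = sample(LETTERS[9:16], 15, replace = TRUE),
                      weight = round(runif(15), 3))
  net <- InteractionNetwork(edges, "ppi_undirected")

  tsv <- tempfile(fileext = ".tsv")
  write_network(net, tsv, format = "tsv")
  back <- read_edge_list(tsv, "ppi_undirected", weight_threshold = NULL)
  expect_equal(back$edges, net$edges)

  # second pass through write+read changes nothing
  tsv2 <- tempfile(fileext = ".tsv")
  write_network(back, tsv2, format = "tsv")
  back2 <- read_edge_list(tsv2, "ppi_undirected", weight_threshold = NULL)
  expect_identical(back2$edges, back$edges)

  sif <- tempfile(fileext = ".sif")
  write_network(net, sif, format = "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), n_edges(net))
  expect_true(all(grepl("\tinteracts\t", lines)))

  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), n_edges(net))

  expect_error(write_network(net, tempfile(), format = "dot"))
})

test_that("bipartite networks reject within-class edges and probe maps validate", {
  nodes <- data.frame(id = c("TF1", "TF2", "G1"),
                      class = c("regulator", "regulator", "gene"))
  expect_error(InteractionNetwork(data.frame(from = "TF1", to = "TF2"),
                                  "regulator_bipartite", nodes = nodes),
               "one node class")

  pm <- write_tsv_lines(c("p1\tTP53", "p2\ttp53", "p3\tEGFR"))
  map <- read_probe_map(pm)
  expect_equal(unname(map[c("p1", "p2")]), c("TP53", "TP53"))
  bad <- write_tsv_lines(c("p1\t"))
  expect_error(read_probe_map(bad))
})
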