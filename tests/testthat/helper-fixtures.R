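# Fixture builders shared across test files. Everything is generated in code
# at test time; files go to tempdir.

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# small expression fixture: genes x samples, with a matching group map
fixture_expression <- function(values = matrix(1:12, 3, 4,
                                 dimnames = list(c("TP53", "BRCA1", "EGFR"),
                                                 paste0("S", 1:4))),
                               groups = c(S1 = "case", S2 = "case",
                                          S3 = "control", S4 = "control")) {
  expr <- c(paste(c("gene", colnames(values)), collapse = "\t"),
            vapply(seq_len(nrow(values)), function(i)
              paste(c(rownames(values)[i], values[i, ]), collapse = "\t"),
              character(1)))
  grp <- paste(names(groups), unname(groups), sep = "\t")
  list(expression = write_tsv_lines(expr), groups = write_tsv_lines(grp),
       values = values)
}

# log2-scale ExpressionMatrix built directly (bypasses file I/O)
log2_matrix <- function(values, groups, condition_id = "COND") {
  ExpressionMatrix(values, groups = groups, condition_id = condition_id,
                   scale = "log2")
}

# matrix with one strongly shifted gene and quiet background
planted_log2_matrix <- function(n_genes = 50, n_case = 10, n_ctrl = 10,
                                planted = "G001", effect = 3, sd = 0.3,
                                seed = 42) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  ids <- c(paste0("case", seq_len(n_case)), paste0("ctrl", seq_len(n_ctrl)))
  v <- matrix(rnorm(n_genes * length(ids), 8, sd), n_genes, length(ids),
              dimnames = list(genes, ids))
  v[planted, seq_len(n_case)] <- v[planted, seq_len(n_case)] + effect
  groups <- setNames(c(rep("case", n_case), rep("control", n_ctrl)), ids)
  log2_matrix(v, groups)
}

# random DEGSet over a shared symbol pool
random_deg_set <- function(id, pool, n_up = 8, n_down = 8) {
  picked <- sample(pool, n_up + n_down)
  deg_set(id, up = picked[seq_len(n_up)], down = picked[-seq_len(n_up)])
}

# exact upper-tail hypergeometric by exhaustive enumeration of all C(N, n)
# draws from a universe whose first K elements are annotated
enum_hypergeom_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# independent textbook BH step-up, written against the definition
reference_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  if (m > 1)
    for (i in (m - 1):1) ranked[i] <- min(ranked[i], ranked[i + 1])
  pmin(ranked, 1)[order(ord)]
}
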