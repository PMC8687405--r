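#' Read an expression matrix with its group map
#'
#' Expression input is tab-separated text: a header row of sample ids, one row
#' per gene/probe with the identifier in the first column. The group map is a
#' two-column TSV (sample id, `case`/`control`) covering every sample.
#'
#' Duplicate gene symbols are retained as separate rows under distinct internal
#' row keys (`SYMBOL`, `SYMBOL.2`, ...) and left for [collapse_probes()];
#' duplicate sample ids are rejected.
#'
#' @param path expression matrix TSV.
#' @param groups_path group map TSV.
#' @param condition_id condition label; defaults to the file name sans
#'   extension.
#' @return An [ExpressionMatrix()] with `scale = "raw"`.
#' @export
read_expression <- function(path, groups_path,
                            condition_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("empty or header-only expression file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (!length(sample_ids)) stop("no sample columns in ", path)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1] + 1L, " has ", nf[nf != length(header)][1],
         " fields, expected ", length(header))
  ids <- toupper(vapply(body, `[[`, character(1), 1L))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- vapply(body, `[[`, character(1), j + 1L)
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1]
      stop("non-numeric value '", col[i], "' at gene '", ids[i],
           "', sample '", sample_ids[j], "'")
    }
    vals[, j] <- num
  }
  rownames(vals) <- make.unique(ids, sep = ".")
  colnames(vals) <- sample_ids
  groups <- read_group_map(groups_path)
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing))
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  ExpressionMatrix(vals, groups = groups[sample_ids],
                   condition_id = condition_id, gene_ids = ids, scale = "raw")
}

#' Read a sample -> case/control group map
#' @param path two-column TSV (sample id, group). No header.
#' @return named character vector.
#' @export
read_group_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("sample", "group"))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad)) stop("group labels must be case/control, got: ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate samples in group map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  stats::setNames(df$group, df$sample)
}

#' Write an expression matrix as TSV
#' @param m an [ExpressionMatrix()].
#' @param path output TSV; first column `gene`, then one column per sample.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = m$gene_ids, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: one set per line — term id, description, then the member
#' genes, all tab-separated. Genes are uppercased; the universe defaults to
#' the union of all sets.
#'
#' @param path GMT file.
#' @param name library label; defaults to the file name.
#' @param universe optional explicit background gene set.
#' @return A [GeneSetLibrary()].
#' @export
read_gmt <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                     universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f)
    list(description = f[2], genes = toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate term ids in GMT: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  GeneSetLibrary(sets, name = name, universe = universe)
}

#' Write a GeneSetLibrary as GMT
#' @param lib a [GeneSetLibrary()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  lines <- vapply(names(lib$sets), function(id) {
    s <- lib$sets[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a network edge list
#'
#' TSV with columns `a`, `b` and, optionally, `weight` (header optional; a
#' header is detected when the third field of the first line is non-numeric or
#' the first two fields are literally `a`/`b` or `from`/`to`). For the PPI
#' kind, weights above 1 are auto-detected as STRING combined scores and
#' divided by 1000 (logged via a message); edges below `weight_threshold` are
#' dropped. Self-loops are dropped with a logged count; undirected edges are
#' canonicalized and deduplicated.
#'
#' @param path edge list TSV.
#' @param kind network kind, see [InteractionNetwork()].
#' @param weight_threshold minimum retained weight in \[0, 1\], or `NULL` for
#'   no filtering. Default 0.4 for PPI (STRING "medium confidence"), `NULL`
#'   otherwise.
#' @return An [InteractionNetwork()].
#' @export
read_edge_list <- function(path, kind,
                           weight_threshold = if (kind == "ppi_undirected") 0.4 else NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(InteractionNetwork(NULL, kind = kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1]]
  # header iff the weight slot is non-numeric, or a weightless two-column
  # file opens with canonical header names
  has_header <- (length(first) >= 3 &&
                   is.na(suppressWarnings(as.numeric(first[3])))) ||
    (length(first) == 2 &&
       (identical(tolower(first), c("a", "b")) ||
          identical(tolower(first), c("from", "to")) ||
          identical(tolower(first), c("source", "target"))))
  if (has_header) fields <- fields[-1]
  if (!length(fields)) return(InteractionNetwork(NULL, kind = kind))
  if (any(lengths(fields) < 2)) stop("edge list line with fewer than 2 fields")
  from <- toupper(vapply(fields, `[[`, character(1), 1L))
  to <- toupper(vapply(fields, `[[`, character(1), 2L))
  weight <- vapply(fields, function(f)
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else 1, numeric(1))
  if (anyNA(weight)) stop("non-numeric weight at line ",
                          which(is.na(weight))[1] + has_header)
  if (kind == "ppi_undirected" && any(weight > 1)) {
    message("PPI weights exceed 1; interpreting as STRING combined scores / 1000")
    weight <- weight / 1000
  }
  if (kind == "ppi_undirected" && any(weight < 0 | weight > 1))
    stop("PPI edge weights must lie in [0, 1] after scaling")
  if (!is.null(weight_threshold)) {
    keep <- weight >= weight_threshold
    from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  }
  net <- InteractionNetwork(data.frame(from = from, to = to, weight = weight,
                                       stringsAsFactors = FALSE), kind = kind)
  if (net$n_self_loops_dropped > 0)
    message(net$n_self_loops_dropped, " self-loop(s) dropped from ", basename(path))
  net
}

#' Write a network to disk
#'
#' `tsv` writes the canonical edge list (losslessly re-readable with
#' [read_edge_list()]); `sif` writes the Cytoscape simple-interaction format
#' (`a <relation> b`); `graphml` writes GraphML.
#'
#' @param net an [InteractionNetwork()].
#' @param path output file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param relation SIF relation label (default `"interacts"`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml"),
                          relation = "interacts") {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- net$edges
    colnames(df) <- c("a", "b", "weight")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    if (nrow(net$edges)) {
      writeLines(paste(net$edges$from, relation, net$edges$to, sep = "\t"), path)
    } else writeLines(character(0), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a probe -> gene symbol map
#' @param path two-column TSV (probe id, symbol), no header. Many-to-one
#'   probe->symbol mappings are allowed; empty symbols are rejected.
#' @return named character vector probe -> uppercased symbol.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("probe", "symbol"))
  if (any(!nzchar(df$symbol))) stop("probe map contains empty symbols")
  if (anyDuplicated(df$probe))
    stop("duplicate probes in map: ",
         paste(unique(df$probe[duplicated(df$probe)]), collapse = ", "))
  stats::setNames(toupper(df$symbol), df$probe)
}
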