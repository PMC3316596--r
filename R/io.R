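#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample labels and a
#' first column of gene labels. Rows sharing a gene label (e.g. multiple
#' probesets for one gene) are collapsed by their per-sample median.
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected gene labels plus at least one sample")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains non-numeric or NA values")
  if (anyDuplicated(genes)) {
    m <- apply(m, 2L, function(col) tapply(col, genes, stats::median))
    m <- m[unique(genes)[order(match(unique(genes), genes))], ,
           drop = FALSE]
  } else {
    rownames(m) <- genes
  }
  m
}

#' Write an expression matrix to TSV
#'
#' @param data genes x samples numeric matrix.
#' @param path output file path.
#' @export
writeExpression <- function(data, path) {
  data <- .exprMatrix(data)
  df <- data.frame(gene = rownames(data), data, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network from a two-column TSV edge list
#'
#' Lines hold two (optionally three: weight) tab-separated fields; a
#' header line is detected by a non-numeric third field named otherwise.
#'
#' @param path file path.
#' @param vertices optional gene universe to include as (possibly
#'   isolated) vertices.
#' @return undirected igraph network.
#' @export
readNetwork <- function(path, vertices = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (length(readLines(path, n = 1L)) == 0L) {
    data.frame()   # empty network file: no edges
  } else {
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(df) && identical(tolower(as.character(df[1, 1:2])),
                            c("from", "to")))
    df <- df[-1L, , drop = FALSE]
  if (!nrow(df)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    d <- data.frame(from = as.character(df[[1L]]),
                    to = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
    if (ncol(df) >= 3L) d$weight <- as.numeric(df[[3L]])
    g <- igraph::graph_from_data_frame(d, directed = FALSE)
  }
  if (!is.null(vertices)) {
    miss <- setdiff(vertices, igraph::V(g)$name)
    if (length(miss)) {
      g <- igraph::add_vertices(g, length(miss), name = miss)
    }
  }
  g
}

#' Write a network as a TSV edge list or GraphML
#'
#' @param network undirected igraph network.
#' @param path output file path.
#' @param format `"tsv"` (two columns, plus `weight` when present) or
#'   `"graphml"` (edge attributes preserved).
#' @export
writeNetwork <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network, names = TRUE)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     stringsAsFactors = FALSE)
    w <- igraph::edge_attr(network, "weight")
    if (!is.null(w)) df$weight <- w
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Each line: term id, description, then tab-separated gene labels. A
#' two-column TSV (term id, gene) is accepted as a fallback and grouped
#' by term.
#'
#' @param path file path.
#' @return named list of gene-label vectors with a `description`
#'   attribute (named character vector).
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 2L)) {
    # two-column fallback: term, gene
    term <- vapply(fields, `[`, character(1), 1L)
    gene <- vapply(fields, `[`, character(1), 2L)
    sets <- split(gene, term)
    attr(sets, "description") <- stats::setNames(names(sets), names(sets))
    return(sets)
  }
  if (any(nf < 3L))
    stop("malformed GMT: every line needs id, description and >= 1 gene")
  ids <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}
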