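# internal helpers shared across modules

# canonical key for an unordered gene pair; "\r" cannot occur in gene labels
# read from TSV, so keys are collision-free
.pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

.edgeKeys <- function(graph) {
  if (igraph::ecount(graph) == 0L) return(character(0))
  el <- igraph::as_edgelist(graph, names = TRUE)
  .pairKey(el[, 1L], el[, 2L])
}

# fan one user-facing seed out into named sub-streams so each stochastic
# stage (null, bootstrap, p-hat estimation, ...) is independently reproducible
.deriveSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 99991
  x <- (as.numeric(seed) %% 2147483647) * 48271 + h * 16807
  as.integer(x %% 2147483647)
}

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

# coerce supported containers to a named genes x samples numeric matrix
.exprMatrix <- function(data) {
  if (methods::is(data, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input requires the SummarizedExperiment package")
    data <- SummarizedExperiment::assay(data, 1L)
  }
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("expression data must be numeric")
  if (is.null(rownames(data)))
    rownames(data) <- sprintf("G%03d", seq_len(nrow(data)))
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("S%03d", seq_len(ncol(data)))
  if (anyDuplicated(rownames(data)))
    stop("duplicate gene labels; collapse them first (see readExpression)")
  data
}

.allPairs <- function(genes) {
  idx <- utils::combn(length(genes), 2L)
  data.frame(gene1 = genes[idx[1L, ]], gene2 = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}
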