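#' Cosine similarity between two feature vectors
#'
#' `k(x_i, x_j) = (x_i . x_j) / (||x_i|| ||x_j||)`, the kernel used to decide
#' which encounters are connected in the patient similarity graph.
#'
#' @param a,b numeric vectors of equal length with non-zero Euclidean norm.
#' @return a scalar in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1)) # 0.5
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for a zero-norm vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Build the patient similarity graph
#'
#' Connects two encounters by an undirected edge (weight 1) whenever the
#' cosine similarity between their feature vectors strictly exceeds
#' `threshold` (default 0.85). Self-loops are never stored; they are added
#' inside the encoder as `A + I`. Similarities are computed blockwise on
#' row-normalised features so the dense N x N similarity matrix is never
#' materialised.
#'
#' @param x an `encounter_matrix` (fully observed; run [impute_cohort()]
#'   first) or a plain numeric matrix.
#' @param threshold cosine cut-off; edges require similarity strictly
#'   greater than this value.
#' @param standardise if `TRUE`, z-score each feature column before
#'   computing similarities.
#' @param block_size rows per block in the pairwise computation.
#' @return an object of class `patient_graph`: a list with `n_nodes`,
#'   `adjacency` (symmetric sparse `Matrix` with zero diagonal; weight 1 per
#'   edge until [assign_clique_weights()] is applied), and `threshold`.
#' @export
build_graph <- function(x, threshold = 0.85, standardise = FALSE,
                        block_size = 1024L) {
  ids <- NULL
  if (inherits(x, "encounter_matrix")) {
    ids <- x$encounter_ids
    x <- x$features
  }
  x <- as.matrix(x)
  if (anyNA(x))
    stop("features contain missing values; impute before building the graph",
         call. = FALSE)
  if (standardise) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  n <- nrow(x)
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    bad <- which(norms == 0)
    lab <- if (!is.null(ids)) ids[bad] else bad
    stop(sprintf("zero-norm feature rows (no basis for cosine similarity): %s",
                 paste(utils::head(lab, 10), collapse = ", ")), call. = FALSE)
  }
  xn <- x / norms

  ii <- integer(0); jj <- integer(0)
  start <- 1L
  while (start <= n) {
    end <- min(start + block_size - 1L, n)
    s <- xn[start:end, , drop = FALSE] %*% t(xn)
    hit <- which(s > threshold, arr.ind = TRUE)
    gi <- hit[, 1] + start - 1L
    gj <- hit[, 2]
    keep <- gi < gj
    ii <- c(ii, gi[keep]); jj <- c(jj, gj[keep])
    start <- end + 1L
  }

  adjacency <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii), x = rep(1, 2 * length(ii)),
    dims = c(n, n)
  )
  new_patient_graph(adjacency, threshold)
}

new_patient_graph <- function(adjacency, threshold = NA_real_) {
  adjacency <- methods::as(adjacency, "CsparseMatrix")
  structure(
    list(
      n_nodes = nrow(adjacency),
      adjacency = adjacency,
      threshold = threshold
    ),
    class = "patient_graph"
  )
}

#' Construct a patient graph from an explicit edge list
#'
#' @param n_nodes number of nodes.
#' @param edges two-column matrix (or data frame) of 1-based node pairs.
#' @param weights optional edge weights (default 1).
#' @return a `patient_graph`.
#' @export
graph_from_edges <- function(n_nodes, edges, weights = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    return(new_patient_graph(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(n_nodes, n_nodes)
    )))
  }
  storage.mode(edges) <- "integer"
  if (any(edges < 1 | edges > n_nodes)) stop("edge endpoint out of range")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  w <- if (is.null(weights)) rep(1, nrow(edges)) else as.numeric(weights)
  adjacency <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = c(w, w), dims = c(n_nodes, n_nodes), use.last.ij = TRUE
  )
  new_patient_graph(adjacency)
}

#' Number of undirected edges in a patient graph
#' @param graph a `patient_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(graph) nrow(edge_table(graph$adjacency))

#' @export
print.patient_graph <- function(x, ...) {
  et <- edge_table(x$adjacency)
  cat(sprintf("<patient_graph> %d nodes, %d undirected edges", x$n_nodes, nrow(et)))
  if (!is.na(x$threshold)) cat(sprintf(" (cosine threshold %g)", x$threshold))
  if (nrow(et) > 0) cat(sprintf("; edge weights in [%g, %g]", min(et$w), max(et$w)))
  cat("\n")
  invisible(x)
}

#' Export / import a patient graph as an edge-list file
#'
#' Plain text, one undirected edge per line: `i<TAB>j<TAB>weight` with
#' 0-based node indices and `i < j`. A header comment records the node count.
#'
#' @param graph a `patient_graph`.
#' @param path file path.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist`
#'   returns a `patient_graph`.
#' @export
write_edgelist <- function(graph, path) {
  et <- edge_table(graph$adjacency)
  lines <- c(
    sprintf("# nodes: %d", graph$n_nodes),
    sprintf("%d\t%d\t%g", et$i - 1L, et$j - 1L, et$w)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  header <- grep("^# nodes:", lines, value = TRUE)
  if (length(header) != 1)
    stop("edge-list file lacks a '# nodes:' header", call. = FALSE)
  n <- as.integer(sub("^# nodes:\\s*", "", header))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) return(graph_from_edges(n, matrix(integer(0), 0, 2)))
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  graph_from_edges(
    n,
    cbind(as.integer(parts[, 1]) + 1L, as.integer(parts[, 2]) + 1L),
    weights = as.numeric(parts[, 3])
  )
}

#' Export a patient graph in MatrixMarket coordinate format
#'
#' @param graph a `patient_graph`.
#' @param path file path (conventionally `.mtx`).
#' @return `path`, invisibly.
#' @export
write_graph_mtx <- function(graph, path) {
  Matrix::writeMM(methods::as(graph$adjacency, "generalMatrix"), path)
  invisible(path)
}

#' @rdname write_graph_mtx
#' @export
read_graph_mtx <- function(path) {
  new_patient_graph(methods::as(Matrix::readMM(path), "CsparseMatrix"))
}
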