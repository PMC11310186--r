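#' Enumerate all maximal cliques (Bron-Kerbosch with pivoting)
#'
#' Lists every maximal clique of the (undirected, topology-only) patient
#' graph exactly once, including isolated nodes as singleton cliques. The
#' recursion keeps the classic three sets — the growing clique `R`, the
#' candidates `P`, and the already-processed set (often written `X` or `Q`);
#' a clique is reported when both `P` and the processed set are empty. A
#' pivot maximising `|P intersect N(pivot)|` (ties broken by lowest node
#' index) prunes the branching, which matters on dense similarity graphs
#' where near-complete clusters would otherwise explode the recursion.
#'
#' Output is normalised for reproducibility: each clique is sorted
#' internally and cliques are ordered lexicographically.
#'
#' @param graph a `patient_graph`; edge weights are ignored.
#' @return an object of class `clique_set`: list with `cliques` (list of
#'   sorted 1-based integer vectors) and `source_graph_hash` binding the
#'   enumeration to the graph it came from.
#' @export
#' @examples
#' g <- graph_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' enumerate_maximal_cliques(g)$cliques # list(c(1, 2, 3))
enumerate_maximal_cliques <- function(graph) {
  stopifnot(inherits(graph, "patient_graph"))
  n <- graph$n_nodes
  a <- methods::as(methods::as(graph$adjacency, "generalMatrix"), "TsparseMatrix")
  if (!Matrix::isSymmetric(graph$adjacency))
    stop("adjacency must be symmetric", call. = FALSE)
  nbr <- vector("list", n)
  keep <- a@x != 0
  ii <- a@i[keep] + 1L
  jj <- a@j[keep] + 1L
  if (length(ii)) {
    ord <- order(ii, jj)
    nbr_split <- split(jj[ord], factor(ii[ord], levels = seq_len(n)))
    nbr <- unname(nbr_split)
  } else {
    nbr <- rep(list(integer(0)), n)
  }

  out <- new.env(parent = emptyenv())
  out$cliques <- vector("list", 64L)
  out$count <- 0L

  report <- function(r) {
    out$count <- out$count + 1L
    if (out$count > length(out$cliques))
      out$cliques <- c(out$cliques, vector("list", length(out$cliques)))
    out$cliques[[out$count]] <- sort(r)
  }

  bk <- function(r, p, q) {
    if (length(p) == 0 && length(q) == 0) {
      report(r)
      return(invisible(NULL))
    }
    # pivot from P union Q with the most candidates among its neighbours
    cand <- c(p, q)
    best <- -1L; pivot <- cand[1]
    for (u in sort(cand)) {
      k <- sum(p %in% nbr[[u]])
      if (k > best) { best <- k; pivot <- u }
    }
    for (v in p[!(p %in% nbr[[pivot]])]) {
      nv <- nbr[[v]]
      bk(c(r, v), p[p %in% nv], q[q %in% nv])
      p <- p[p != v]
      q <- c(q, v)
    }
    invisible(NULL)
  }

  bk(integer(0), seq_len(n), integer(0))
  cliques <- out$cliques[seq_len(out$count)]

  # lexicographic normalisation
  key <- vapply(cliques, function(cl) paste(sprintf("%09d", cl), collapse = ","),
                character(1))
  cliques <- cliques[order(key)]

  structure(
    list(cliques = cliques, source_graph_hash = graph_digest(graph)),
    class = "clique_set"
  )
}

#' @export
print.clique_set <- function(x, ...) {
  sizes <- lengths(x$cliques)
  cat(sprintf("<clique_set> %d maximal cliques (sizes %d..%d)\n",
              length(x$cliques),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Re-weight graph edges by maximal-clique membership
#'
#' Sets the weight of every edge (i, j) to `c` when the largest maximal
#' clique containing both endpoints has `c + 1` nodes, so strongly
#' cohesive patient groups dominate the encoder's neighbourhood averaging.
#' An edge belonging to several maximal cliques takes, by default, the
#' maximum such `c` (alternatives: `"sum"` and `"count"` over containing
#' cliques). The edge set itself is never changed: every edge lies in some
#' maximal clique of size >= 2, so all weights are >= 1. Weights from a
#' previous call are reset, making the operation idempotent.
#'
#' @param graph the `patient_graph` the cliques were enumerated from.
#' @param clique_set the matching [enumerate_maximal_cliques()] result.
#' @param aggregator how to combine multiple clique memberships of an edge:
#'   `"max"` (default), `"sum"`, or `"count"`.
#' @return the graph with integer clique weights on its edges.
#' @export
assign_clique_weights <- function(graph, clique_set,
                                  aggregator = c("max", "sum", "count")) {
  stopifnot(inherits(graph, "patient_graph"), inherits(clique_set, "clique_set"))
  aggregator <- match.arg(aggregator)
  if (!identical(clique_set$source_graph_hash, graph_digest(graph)))
    stop("stale clique set: it was not computed from this graph", call. = FALSE)

  et <- edge_table(graph$adjacency)
  if (nrow(et) == 0) return(graph)
  n <- graph$n_nodes

  keys <- numeric(0); vals <- numeric(0)
  for (cl in clique_set$cliques) {
    k <- length(cl)
    if (k < 2) next
    pr <- utils::combn(cl, 2L)
    keys <- c(keys, pair_to_index(pr[1, ], pr[2, ], n))
    vals <- c(vals, rep(if (aggregator == "count") 1 else k - 1, ncol(pr)))
  }
  agg_fun <- switch(aggregator, max = max, sum = sum, count = sum)
  w_by_key <- tapply(vals, sprintf("%.0f", keys), agg_fun)

  ekey <- sprintf("%.0f", pair_to_index(et$i, et$j, n))
  w <- as.numeric(w_by_key[ekey])
  if (anyNA(w))
    stop("internal error: an edge of the graph lies in no maximal clique")

  adjacency <- Matrix::sparseMatrix(
    i = c(et$i, et$j), j = c(et$j, et$i), x = c(w, w), dims = c(n, n)
  )
  g <- new_patient_graph(adjacency, graph$threshold)
  g
}

#' Flatten all edge weights to 1
#'
#' The "without clique weighting" ablation: keeps the edge set but discards
#' clique-derived weights.
#'
#' @param graph a `patient_graph`.
#' @return the graph with unit weights.
#' @export
flatten_weights <- function(graph) {
  a <- graph$adjacency
  a@x[a@x != 0] <- 1
  new_patient_graph(a, graph$threshold)
}

#' Write / read a clique set as plain text
#'
#' One clique per line: space-separated, sorted, 0-based node indices.
#'
#' @param clique_set a `clique_set`.
#' @param path file path.
#' @param graph optionally, the graph to re-bind the cliques to on read.
#' @return `write_cliques` returns `path` invisibly; `read_cliques` a
#'   `clique_set` (hash taken from `graph` when supplied).
#' @export
write_cliques <- function(clique_set, path) {
  lines <- vapply(clique_set$cliques,
                  function(cl) paste(cl - 1L, collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cliques
#' @export
read_cliques <- function(path, graph = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cliques <- lapply(strsplit(lines, " ", fixed = TRUE),
                    function(s) sort(as.integer(s) + 1L))
  structure(
    list(
      cliques = cliques,
      source_graph_hash = if (is.null(graph)) NA_character_ else graph_digest(graph)
    ),
    class = "clique_set"
  )
}
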