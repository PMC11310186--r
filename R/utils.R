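# Internal helpers: seeded sub-streams, RNG localisation, triangular pair
# indexing, and canonical graph digests.

#' Derive a reproducible sub-stream seed
#'
#' A master seed plus a stream name (and optional index, e.g. an epoch or
#' repeat number) is mapped deterministically to an integer seed below 2^31.
#' Named sub-streams keep the randomness of independent components (splits,
#' parameter init, Edge Flux, mini-batch order) decoupled, so that e.g. the
#' ablation without Edge Flux consumes exactly the same split/init/batch
#' randomness as the full model.
#'
#' @param seed master integer seed.
#' @param stream character stream label.
#' @param index optional non-negative integer (epoch, repeat, ...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(abs(as.double(seed)) %% m)
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  h <- (h * 31 + as.double(index)) %% m
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Linear indexing of unordered pairs (i < j) over n nodes, row-major:
# pair (i, j) -> k in 1..n(n-1)/2. Used to sample absent edges without
# materialising the O(n^2) pair set.
pair_to_index <- function(i, j, n) {
  (i - 1) * n - i * (i + 1) / 2 + j
}

index_to_pair <- function(k, n) {
  # invert the row-major triangular enumeration
  i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * (k - 1))) / 2) + 1
  j <- k - ((i - 1) * n - i * (i + 1) / 2)
  # guard floating-point rounding at block boundaries
  fix <- j <= i
  while (any(fix)) {
    i[fix] <- i[fix] - 1
    j[fix] <- k[fix] - ((i[fix] - 1) * n - i[fix] * (i[fix] + 1) / 2)
    fix <- j <= i
  }
  over <- j > n
  while (any(over)) {
    i[over] <- i[over] + 1
    j[over] <- k[over] - ((i[over] - 1) * n - i[over] * (i[over] + 1) / 2)
    over <- j > n
  }
  cbind(i = i, j = j)
}

# Canonical upper-triangular edge data frame (1-based i < j, weight) of a
# patient graph; the basis for digests, exports, and Edge Flux sampling.
edge_table <- function(adjacency) {
  a <- methods::as(methods::as(adjacency, "generalMatrix"), "TsparseMatrix")
  i <- a@i + 1L
  j <- a@j + 1L
  w <- a@x
  keep <- i < j & w != 0
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  o <- order(i, j)
  data.frame(i = i[o], j = j[o], w = w[o])
}

# Digest binding a clique set (or other artefact) to the exact graph it was
# computed from.
graph_digest <- function(graph) {
  et <- edge_table(graph$adjacency)
  rlang::hash(list(n = graph$n_nodes, i = et$i, j = et$j, w = et$w))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
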