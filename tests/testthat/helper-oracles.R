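# Independent reference implementations used as oracles. Deliberately naive:
# exhaustive enumeration and explicit loops, sharing no code with the package.

# All maximal cliques of a small graph (n <= ~14) by exhaustive subset
# enumeration over vertex bitmasks.
brute_force_max_cliques <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  masks <- integer(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] != 0)
    nb <- nb[nb != v]
    masks[v] <- sum(bitwShiftL(1L, nb - 1L))
  }
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  cliques <- list()
  for (S in seq_len(2^n) - 1L) {
    if (S == 0L) next
    vs <- which(bitwAnd(bit, S) != 0L)
    ok <- TRUE
    for (v in vs) {
      others <- S - bit[v]
      if (bitwAnd(masks[v], others) != others) { ok <- FALSE; break }
    }
    if (!ok) next
    maximal <- TRUE
    for (u in setdiff(seq_len(n), vs)) {
      if (bitwAnd(masks[u], S) == S) { maximal <- FALSE; break }
    }
    if (maximal) cliques[[length(cliques) + 1L]] <- vs
  }
  key <- vapply(cliques, function(cl) paste(sprintf("%09d", cl), collapse = ","),
                character(1))
  cliques[order(key)]
}

# Area under the PR curve by an explicit threshold sweep with full
# recounting at every distinct score.
brute_force_auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# Thresholded-cosine graph by a naive double loop.
naive_similarity_graph <- function(x, threshold) {
  n <- nrow(x)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- sum(x[i, ] * x[j, ]) / (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2)))
      if (s > threshold) adj[i, j] <- 1
    }
  }
  adj
}

# Erdos-Renyi patient_graph fixture.
random_er_graph <- function(n, p, seed) {
  set.seed(seed)
  edges <- t(combn(n, 2))
  keep <- runif(nrow(edges)) < p
  graph_from_edges(n, edges[keep, , drop = FALSE])
}

# Random positively-weighted patient_graph fixture.
random_weighted_graph <- function(n, p, seed, max_w = 5) {
  set.seed(seed)
  edges <- t(combn(n, 2))
  keep <- runif(nrow(edges)) < p
  edges <- edges[keep, , drop = FALSE]
  graph_from_edges(n, edges, weights = sample(max_w, nrow(edges), replace = TRUE))
}

# Small fully-observed cohort fixture for encoder/training tests.
tiny_cohort <- function(n = 120, seed = 42, strength = 1.0, clusters = 4) {
  impute_cohort(generate_cohort(cohort_spec(
    n_encounters = n, n_clusters = clusters, n_code_features = 80,
    codes_per_cluster = 12, cluster_outcome_strength = strength,
    missing_rate = 0.03, seed = seed
  )))
}
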