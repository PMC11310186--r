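#' Configure Edge Flux
#'
#' Edge Flux perturbs the patient graph once per training epoch: each absent
#' node pair gains an edge with probability `p_add`, each existing edge is
#' deleted with probability `p_delete`, and everything else is unchanged.
#' The perturbation regularises training on the graph structure, letting the
#' model see plausible unobserved patient similarities and survive the loss
#' of observed ones.
#'
#' Defaults keep the expected perturbation a small fraction of the edge set
#' on sparse graphs; both are ordinary tuning knobs.
#'
#' @param p_add probability of adding an absent edge, in \[0, 1\].
#' @param p_delete probability of deleting an existing edge, in \[0, 1\].
#' @param seed integer seed for the flux randomness stream.
#' @return an object of class `flux_config`.
#' @export
flux_config <- function(p_add = 0.01, p_delete = 0.05, seed = 1L) {
  if (!is.finite(p_add) || p_add < 0 || p_add > 1)
    stop_field("p_add", "must be in [0, 1]")
  if (!is.finite(p_delete) || p_delete < 0 || p_delete > 1)
    stop_field("p_delete", "must be in [0, 1]")
  structure(
    list(p_add = as.numeric(p_add), p_delete = as.numeric(p_delete),
         seed = as.integer(seed)),
    class = "flux_config"
  )
}

#' Apply one epoch of Edge Flux
#'
#' Samples the perturbation per unordered node pair and mirrors it, so the
#' output adjacency stays symmetric. Surviving edges keep their clique
#' weights; added edges get weight 1 (no clique membership is known for
#' them — cliques are not re-enumerated during training). The randomness is
#' a deterministic function of `(cfg$seed, epoch)`, and flux is always
#' applied to the pristine clique-weighted graph, never compounded across
#' epochs.
#'
#' Absent pairs are sampled by drawing a Binomial(M - |E|, p_add) count and
#' then that many uniform absent pairs, which is distributionally equivalent
#' to per-pair Bernoulli draws without an O(N^2) scan.
#'
#' @param graph the original (clique-weighted) `patient_graph`.
#' @param cfg a [flux_config()].
#' @param epoch integer epoch number (selects the randomness sub-stream).
#' @return the perturbed `patient_graph`.
#' @export
apply_edge_flux <- function(graph, cfg, epoch = 1L) {
  stopifnot(inherits(graph, "patient_graph"), inherits(cfg, "flux_config"))
  if (cfg$p_add == 0 && cfg$p_delete == 0) return(graph)
  n <- graph$n_nodes
  et <- edge_table(graph$adjacency)
  m_total <- n * (n - 1) / 2
  m_edges <- nrow(et)

  with_local_seed(derive_seed(cfg$seed, "edge_flux", epoch), {
    keep <- if (m_edges > 0) stats::runif(m_edges) >= cfg$p_delete else logical(0)

    n_absent <- m_total - m_edges
    n_add <- if (n_absent > 0 && cfg$p_add > 0) {
      stats::rbinom(1L, size = n_absent, prob = cfg$p_add)
    } else 0L

    add_idx <- numeric(0)
    if (n_add > 0) {
      present <- pair_to_index(et$i, et$j, n)
      chosen <- numeric(0)
      # rejection-sample uniform absent pairs among all M linear indices
      while (length(chosen) < n_add) {
        need <- n_add - length(chosen)
        cand <- sample(m_total, size = min(m_total, need * 2L + 10L))
        cand <- cand[!(cand %in% present) & !(cand %in% chosen)]
        chosen <- c(chosen, utils::head(cand, need))
      }
      add_idx <- chosen
    }

    ei <- et$i[keep]; ej <- et$j[keep]; ew <- et$w[keep]
    if (length(add_idx)) {
      ap <- index_to_pair(add_idx, n)
      ei <- c(ei, ap[, "i"]); ej <- c(ej, ap[, "j"]); ew <- c(ew, rep(1, nrow(ap)))
    }
    adjacency <- Matrix::sparseMatrix(
      i = c(ei, ej), j = c(ej, ei), x = c(ew, ew), dims = c(n, n)
    )
    new_patient_graph(adjacency, graph$threshold)
  })
}
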