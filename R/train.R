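#' Configure a training run
#'
#' Defaults follow the standard setup for this model family: Adam with a
#' fixed learning rate of 0.001, mini-batches of 128 training nodes, 250
#' epochs, and evaluation repeated 5 times over fresh random splits.
#' Mini-batches partition the *training* nodes for loss and gradient
#' purposes; every forward pass uses the whole graph (transductive message
#' passing).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size training nodes per mini-batch.
#' @param epochs training epochs; Edge Flux redraws the graph once per epoch.
#' @param split_fractions `c(train, val, test)` summing to 1.
#' @param n_repeats independent (split, init, flux) repetitions.
#' @param flux a [flux_config()].
#' @param ablation `"full"`, `"no_edge_flux"`, or `"no_clique"`.
#' @param hidden_dim embedding dimension of the encoder.
#' @param threshold cosine threshold used when a graph must be built.
#' @param seed master seed; all sub-streams (splits, init, flux, batching)
#'   are derived from it.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001,
                         batch_size = 128L,
                         epochs = 250L,
                         split_fractions = c(0.7, 0.15, 0.15),
                         n_repeats = 5L,
                         flux = flux_config(),
                         ablation = c("full", "no_edge_flux", "no_clique"),
                         hidden_dim = 16L,
                         threshold = 0.85,
                         seed = 1L) {
  ablation <- match.arg(ablation)
  split_fractions <- as.numeric(split_fractions)
  if (length(split_fractions) != 3 || any(split_fractions <= 0))
    stop_field("split_fractions", "must be three positive fractions")
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop_field("split_fractions", "must sum to 1")
  if (learning_rate <= 0) stop_field("learning_rate", "must be positive")
  if (batch_size < 1) stop_field("batch_size", "must be a positive integer")
  if (epochs < 1) stop_field("epochs", "must be a positive integer")
  if (n_repeats < 1) stop_field("n_repeats", "must be a positive integer")
  structure(
    list(
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      split_fractions = split_fractions,
      n_repeats = as.integer(n_repeats),
      flux = flux,
      ablation = ablation,
      hidden_dim = as.integer(hidden_dim),
      threshold = as.numeric(threshold),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' The four standard split regimes
#'
#' Train/validation/test fractions probing data-rich through data-scarce
#' label regimes: 70/15/15, 40/30/30, 30/35/35, 20/40/40.
#'
#' @return a named list of length-3 fraction vectors.
#' @export
split_regimes <- function() {
  list(
    "70/15/15" = c(0.70, 0.15, 0.15),
    "40/30/30" = c(0.40, 0.30, 0.30),
    "30/35/35" = c(0.30, 0.35, 0.35),
    "20/40/40" = c(0.20, 0.40, 0.40)
  )
}

#' Randomly partition nodes into train/validation/test sets
#'
#' Split sizes are the fraction counts rounded by the largest-remainder
#' rule, so they always sum to `n`; the partition is disjoint and
#' exhaustive, keeping evaluation encounters out of training entirely.
#'
#' @param n number of nodes.
#' @param fractions `c(train, val, test)` positive, summing to 1.
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
make_splits <- function(n, fractions, seed = 1L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive values summing to 1", call. = FALSE)
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- raw - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1
  }
  if (any(sizes == 0))
    stop("a split is empty; increase n or the smallest fraction", call. = FALSE)
  with_local_seed(seed, {
    perm <- sample.int(n)
    list(
      train = sort(perm[seq_len(sizes[1])]),
      val = sort(perm[sizes[1] + seq_len(sizes[2])]),
      test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
    )
  })
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: thresholds sweep the distinct scores in
#' descending order (tied scores form a single threshold), and the area is
#' the sum of precision-weighted recall increments. For constant scores this
#' equals the positive prevalence, the no-skill baseline. Preferred over ROC
#' AUC for heavily imbalanced outcomes such as ICU mortality.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return scalar in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels))
    stop("AUPRC is undefined when only one class is present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE) # last index within each tie group
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Train the encoder on a patient graph
#'
#' Runs the full loop: each epoch draws a perturbed graph via
#' [apply_edge_flux()] (unless `ablation = "no_edge_flux"`), partitions the
#' shuffled training nodes into mini-batches, computes full-graph embeddings
#' on the perturbed adjacency with BCE loss on each batch's labelled nodes
#' only, and applies an Adam update. The checkpoint with the best validation
#' AUPRC is retained; validation (and any later evaluation) uses the
#' pristine, unperturbed graph. Test labels are never touched: test nodes
#' participate in message passing only through their features (transductive
#' evaluation).
#'
#' @param x node features (matrix or `encounter_matrix`; must be fully
#'   observed).
#' @param graph the clique-weighted `patient_graph`.
#' @param labels 0/1 outcome vector; both classes must be present among
#'   training and validation nodes.
#' @param cfg a [train_config()].
#' @param splits optional [make_splits()] result; derived from `cfg$seed`
#'   when absent.
#' @return list with `model` (best-validation checkpoint), `final_model`,
#'   `best_epoch`, `best_val_auprc`, `history` (per-epoch data frame of
#'   train/val loss and val AUPRC), and `splits`.
#' @export
train <- function(x, graph, labels, cfg, splits = NULL) {
  if (inherits(x, "encounter_matrix")) x <- x$features
  stopifnot(inherits(graph, "patient_graph"), inherits(cfg, "train_config"))
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  n <- nrow(x)
  if (graph$n_nodes != n || length(labels) != n)
    stop("features, graph, and labels must agree on the number of encounters",
         call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("labels contain a single class; AUPRC-based model selection is undefined",
         call. = FALSE)
  if (is.null(splits))
    splits <- make_splits(n, cfg$split_fractions, derive_seed(cfg$seed, "splits"))
  if (length(unique(labels[splits$val])) < 2)
    stop("validation split contains a single class", call. = FALSE)

  if (cfg$ablation == "no_clique") graph <- flatten_weights(graph)
  p_clean <- propagation_operator(graph$adjacency)

  model <- encoder_model(ncol(x), cfg$hidden_dim, derive_seed(cfg$seed, "init"))
  state <- adam_state(model)

  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        val_loss = NA_real_, val_auprc = NA_real_)
  best <- list(model = model, epoch = 0L, val_auprc = -Inf)

  for (epoch in seq_len(cfg$epochs)) {
    g_epoch <- if (cfg$ablation == "no_edge_flux") graph else
      apply_edge_flux(graph, cfg$flux, epoch)
    p <- if (cfg$ablation == "no_edge_flux") p_clean else
      propagation_operator(g_epoch$adjacency)

    batch_order <- with_local_seed(
      derive_seed(cfg$seed, "batches", epoch),
      sample(splits$train)
    )
    batches <- split(batch_order,
                     ceiling(seq_along(batch_order) / cfg$batch_size))

    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      fb <- model_gradients(p, x, labels, batches[[bi]], model)
      if (!is.finite(fb$loss))
        stop(sprintf(
          "NaN/Inf loss at epoch %d, batch %d (learning rate %g); training aborted",
          epoch, bi, cfg$learning_rate), call. = FALSE)
      upd <- adam_step(model, fb$grads, state, cfg$learning_rate)
      model <- upd$model
      state <- upd$state
      if (!all(vapply(model[c("theta1", "theta2", "head_w", "head_b")],
                      function(p) all(is.finite(p)), logical(1))))
        stop(sprintf("non-finite parameters after epoch %d, batch %d", epoch, bi),
             call. = FALSE)
      losses[bi] <- fb$loss
    }

    pred <- predict_scores(encode(x, graph, model), model)
    history$train_loss[epoch] <- mean(losses)
    history$val_loss[epoch] <- bce_loss(pred$scores[splits$val],
                                        labels[splits$val])
    history$val_auprc[epoch] <- auprc(pred$scores[splits$val],
                                      labels[splits$val])
    if (history$val_auprc[epoch] > best$val_auprc) {
      best <- list(model = model, epoch = epoch,
                   val_auprc = history$val_auprc[epoch])
    }
  }

  list(
    model = best$model,
    final_model = model,
    best_epoch = best$epoch,
    best_val_auprc = best$val_auprc,
    history = history,
    splits = splits
  )
}

#' Run a repeated train/evaluate experiment
#'
#' Builds the similarity graph and clique weights once, then performs
#' `cfg$n_repeats` independent repetitions, each with its own random split,
#' parameter initialisation, and Edge Flux stream derived from the master
#' seed. Each repetition reports the test AUPRC of its best-validation
#' checkpoint; the result carries the per-repeat values with their mean and
#' standard deviation.
#'
#' @param cohort an `encounter_matrix` (imputed automatically if it contains
#'   missing values).
#' @param cfg a [train_config()].
#' @param graph optionally a pre-built clique-weighted `patient_graph`
#'   (skips graph construction; ablations still apply).
#' @return an object of class `run_result`.
#' @export
run_experiment <- function(cohort, cfg, graph = NULL) {
  stopifnot(inherits(cohort, "encounter_matrix"), inherits(cfg, "train_config"))
  if (anyNA(cohort$features)) cohort <- impute_cohort(cohort)
  x <- cohort$features
  labels <- as.numeric(cohort$labels)

  if (is.null(graph)) {
    graph <- build_graph(cohort, threshold = cfg$threshold)
    graph <- assign_clique_weights(graph, enumerate_maximal_cliques(graph))
  }
  # the ablation without clique weighting runs (and is evaluated) on unit
  # weights over the same edge set
  if (cfg$ablation == "no_clique") graph <- flatten_weights(graph)

  per_repeat <- numeric(cfg$n_repeats)
  best_epochs <- integer(cfg$n_repeats)
  histories <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    rep_cfg <- cfg
    rep_cfg$seed <- derive_seed(cfg$seed, "repeat", r)
    rep_cfg$flux$seed <- derive_seed(cfg$seed, "repeat_flux", r)
    fit <- train(x, graph, labels, rep_cfg)
    pred <- predict_scores(encode(x, graph, fit$model), fit$model)
    per_repeat[r] <- auprc(pred$scores[fit$splits$test], labels[fit$splits$test])
    best_epochs[r] <- fit$best_epoch
    histories[[r]] <- fit$history
  }

  structure(
    list(
      per_repeat_auprc = per_repeat,
      mean_auprc = mean(per_repeat),
      std_auprc = if (cfg$n_repeats > 1) stats::sd(per_repeat) else 0,
      best_epoch = best_epochs,
      loss_history = histories,
      config = cfg
    ),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<run_result> %s, split %s, %d repeats\n  test AUPRC %.4f +/- %.4f  (per repeat: %s)\n",
    cfg$ablation,
    paste(round(100 * cfg$split_fractions), collapse = "/"),
    length(x$per_repeat_auprc),
    x$mean_auprc, x$std_auprc,
    paste(sprintf("%.4f", x$per_repeat_auprc), collapse = ", ")
  ))
  invisible(x)
}

#' Sweep split regimes and/or ablations
#'
#' Runs [run_experiment()] for each requested split regime and ablation and
#' tabulates mean +/- std test AUPRC — the usual report shape for comparing
#' data-rich against data-scarce label regimes and for the ablation study
#' (without Edge Flux; without clique weighting).
#'
#' @param cohort an `encounter_matrix`.
#' @param cfg base [train_config()].
#' @param regimes named list of split fraction triples (default
#'   [split_regimes()]).
#' @param ablations character vector of ablation names.
#' @return data frame with columns `regime`, `ablation`, `mean_auprc`,
#'   `std_auprc`, and per-repeat AUPRCs in a list column `per_repeat`.
#' @export
run_sweep <- function(cohort, cfg, regimes = split_regimes(),
                      ablations = "full") {
  if (anyNA(cohort$features)) cohort <- impute_cohort(cohort)
  graph <- build_graph(cohort, threshold = cfg$threshold)
  graph <- assign_clique_weights(graph, enumerate_maximal_cliques(graph))
  rows <- list()
  for (rg in names(regimes)) {
    for (ab in ablations) {
      cfg_i <- cfg
      cfg_i$split_fractions <- regimes[[rg]]
      cfg_i$ablation <- ab
      res <- run_experiment(cohort, cfg_i, graph = graph)
      rows[[length(rows) + 1]] <- data.frame(
        regime = rg, ablation = ab,
        mean_auprc = res$mean_auprc, std_auprc = res$std_auprc
      )
      rows[[length(rows)]]$per_repeat <- list(res$per_repeat_auprc)
    }
  }
  do.call(rbind, rows)
}
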