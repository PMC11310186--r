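test_that("splits follow largest-remainder sizes and are disjoint-exhaustive", {
  s <- make_splits(10, c(0.7, 0.15, 0.15), seed = 1)
  expect_equal(lengths(s), c(train = 7L, val = 2L, test = 1L))

  s <- make_splits(100, c(0.2, 0.4, 0.4), seed = 2)
  expect_equal(unname(lengths(s)), c(20L, 40L, 40L))

  for (regime in split_regimes()) {
    for (n in c(40, 137, 500)) {
      s <- make_splits(n, regime, seed = n)
      all_idx <- c(s$train, s$val, s$test)
      expect_equal(sort(all_idx), seq_len(n))
      expect_identical(anyDuplicated(all_idx), 0L)
    }
  }

  expect_identical(make_splits(50, c(0.5, 0.25, 0.25), seed = 7),
                   make_splits(50, c(0.5, 0.25, 0.25), seed = 7))
  expect_error(make_splits(4, c(0.9, 0.05, 0.05), seed = 1), "empty")
  expect_error(make_splits(10, c(0.5, 0.5, 0.5), seed = 1), "summing to 1")
})

test_that("auprc matches hand-evaluated step curves", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)

  # reversed ranking: thresholds 0.9, 0.8, 0.2, 0.1 give precision 0, 0,
  # 1/3, 2/4 at recall 0, 0, 1/2, 1 -> AP = 1/3 * 1/2 + 1/2 * 1/2
  expect_equal(auprc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)),
               (1 / 3) * 0.5 + 0.5 * 0.5)

  # constant scores: single threshold, precision = prevalence
  expect_equal(auprc(rep(0.4, 10), c(rep(1, 3), rep(0, 7))), 0.3)

  expect_error(auprc(runif(5), rep(1, 5)), "one class")
})

test_that("auprc agrees with the brute-force threshold sweep", {
  set.seed(606)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    labels <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- if (rep %% 3 == 0) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE) # heavy ties
    } else {
      runif(n)
    }
    expect_equal(auprc(scores, labels), brute_force_auprc(scores, labels),
                 tolerance = 1e-10)
  }
})

test_that("training rejects degenerate inputs", {
  co <- tiny_cohort(n = 60, seed = 5)
  g <- build_graph(co)
  cfg <- train_config(epochs = 2, n_repeats = 1, seed = 1)
  y_const <- rep(1, 60)
  expect_error(train(co$features, g, y_const, cfg), "single class")
  expect_error(train(co$features[1:30, ], g, co$labels[1:30], cfg),
               "number of encounters")
})

test_that("training learns a separable cohort and records history", {
  co <- tiny_cohort(n = 150, seed = 20, strength = 1.0)
  g0 <- build_graph(co)
  g <- assign_clique_weights(g0, enumerate_maximal_cliques(g0))
  cfg <- train_config(epochs = 60, n_repeats = 1, seed = 2,
                      flux = flux_config(0.01, 0.05, seed = 3))
  fit <- train(co$features, g, co$labels, cfg)

  expect_equal(nrow(fit$history), 60)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_gt(fit$best_val_auprc, 0.85)
  expect_lt(min(fit$history$train_loss), 0.25)

  pred <- predict_scores(encode(co$features, g, fit$model), fit$model)
  expect_gt(auprc(pred$scores[fit$splits$test], co$labels[fit$splits$test]),
            0.8)
})

test_that("run_experiment is deterministic and mean/std are consistent", {
  co <- tiny_cohort(n = 100, seed = 31, strength = 0.9)
  cfg <- train_config(epochs = 10, n_repeats = 3, seed = 11)
  a <- run_experiment(co, cfg)
  b <- run_experiment(co, cfg)
  expect_identical(a$per_repeat_auprc, b$per_repeat_auprc)

  expect_length(a$per_repeat_auprc, 3)
  expect_equal(a$mean_auprc, mean(a$per_repeat_auprc), tolerance = 1e-12)
  expect_equal(a$std_auprc, sd(a$per_repeat_auprc), tolerance = 1e-12)

  cfg1 <- train_config(epochs = 5, n_repeats = 1, seed = 4)
  r1 <- run_experiment(co, cfg1)
  expect_equal(r1$std_auprc, 0)
})

test_that("no-flux ablation is bit-identical to full when flux is disabled", {
  co <- tiny_cohort(n = 90, seed = 12, strength = 0.9)
  g0 <- build_graph(co)
  g <- assign_clique_weights(g0, enumerate_maximal_cliques(g0))

  cfg_full <- train_config(epochs = 8, n_repeats = 2, seed = 5,
                           flux = flux_config(0, 0), ablation = "full")
  cfg_noflux <- cfg_full
  cfg_noflux$ablation <- "no_edge_flux"

  a <- run_experiment(co, cfg_full, graph = g)
  b <- run_experiment(co, cfg_noflux, graph = g)
  expect_identical(a$per_repeat_auprc, b$per_repeat_auprc)
})

test_that("no-clique ablation trains on unit weights over the same edge set", {
  co <- tiny_cohort(n = 90, seed = 12, strength = 0.9)
  g0 <- build_graph(co)
  g <- assign_clique_weights(g0, enumerate_maximal_cliques(g0))
  expect_gt(max(edge_table(g$adjacency)$w), 1) # weighting actually did something

  cfg_nc <- train_config(epochs = 8, n_repeats = 2, seed = 5,
                         ablation = "no_clique")
  a <- run_experiment(co, cfg_nc, graph = g)
  b <- run_experiment(co, cfg_nc, graph = flatten_weights(g))
  expect_identical(a$per_repeat_auprc, b$per_repeat_auprc)

  flat <- flatten_weights(g)
  expect_true(all(edge_table(flat$adjacency)$w == 1))
  e0 <- edge_table(g$adjacency)
  e1 <- edge_table(flat$adjacency)
  expect_equal(e1[, c("i", "j")], e0[, c("i", "j")])
})

test_that("run_sweep tabulates regimes by mean and std AUPRC", {
  co <- tiny_cohort(n = 100, seed = 3, strength = 0.9)
  cfg <- train_config(epochs = 6, n_repeats = 2, seed = 8)
  tab <- run_sweep(co, cfg,
                   regimes = split_regimes()[c("70/15/15", "20/40/40")],
                   ablations = c("full", "no_clique"))
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$regime, c("70/15/15", "20/40/40"))
  expect_true(all(tab$mean_auprc >= 0 & tab$mean_auprc <= 1))
  expect_true(all(lengths(tab$per_repeat) == 2))
})
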