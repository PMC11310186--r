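test_that("invalid specs are rejected with the offending field named", {
  expect_error(cohort_spec(0), "n_encounters")
  expect_error(cohort_spec(10, positive_rate = 0), "positive_rate")
  expect_error(cohort_spec(10, positive_rate = 1), "positive_rate")
  expect_error(cohort_spec(5, n_clusters = 6), "n_clusters")
  expect_error(cohort_spec(10, missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(10, cluster_outcome_strength = 1.2),
               "cluster_outcome_strength")
  expect_error(
    cohort_spec(10, n_code_features = 50, n_clusters = 5, codes_per_cluster = 16),
    "codes_per_cluster"
  )
})

test_that("generation is deterministic and honours the spec's shape", {
  spec <- cohort_spec(n_encounters = 150, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)

  expect_equal(dim(a$features), c(150, 204))
  expect_true(all(a$labels %in% c(0L, 1L)))
  expect_length(a$encounter_ids, 150)
  expect_identical(anyDuplicated(a$encounter_ids), 0L)
  expect_setequal(unique(a$feature_kinds), c("categorical", "numeric"))
})

test_that("positive counts stay inside the binomial 99.9% interval", {
  # qbinom(c(5e-4, 1 - 5e-4), 100, 0.15) = [4, 27]; the spec's stated
  # interval [5, 25] is the one asserted
  co <- generate_cohort(cohort_spec(n_encounters = 100, positive_rate = 0.15,
                                    seed = 7))
  expect_gte(sum(co$labels), 5)
  expect_lte(sum(co$labels), 25)

  for (sd in 1:5) {
    co <- generate_cohort(cohort_spec(n_encounters = 400, positive_rate = 0.12,
                                      cluster_outcome_strength = 0.7, seed = sd))
    se <- sqrt(0.12 * 0.88 / 400)
    expect_lt(abs(mean(co$labels) - 0.12), 3 * se + 1e-12)
  }
})

test_that("missing_rate = 0 yields a fully observed matrix", {
  co <- generate_cohort(cohort_spec(n_encounters = 60, missing_rate = 0, seed = 2))
  expect_false(anyNA(co$features))
})

test_that("cluster structure separates cosine similarity within vs between", {
  co <- generate_cohort(cohort_spec(n_encounters = 100, n_clusters = 4,
                                    missing_rate = 0, seed = 9))
  x <- co$features
  cl <- co$clusters
  pick <- utils::combn(40, 2)
  sims <- apply(pick, 2, function(p) cosine_similarity(x[p[1], ], x[p[2], ]))
  same <- cl[pick[1, ]] == cl[pick[2, ]]
  expect_gt(min(sims[same]), max(sims[!same]))
})

test_that("outcome strength dial spans determined to independent labels", {
  co1 <- generate_cohort(cohort_spec(n_encounters = 300,
                                     cluster_outcome_strength = 1.0,
                                     n_noise_flips = 0L, seed = 4))
  per_cluster <- tapply(co1$labels, co1$clusters, function(v) length(unique(v)))
  expect_true(all(per_cluster == 1))

  co0 <- generate_cohort(cohort_spec(n_encounters = 10000,
                                     cluster_outcome_strength = 0.0, seed = 13))
  p <- stats::chisq.test(table(co0$clusters, co0$labels))$p.value
  expect_gt(p, 0.01)
})

test_that("imputation fills numeric means and categorical modes", {
  co <- generate_cohort(cohort_spec(n_encounters = 30, n_numeric_features = 2,
                                    n_code_features = 40, n_clusters = 2,
                                    codes_per_cluster = 10, missing_rate = 0,
                                    seed = 1))
  co$features[1, "num_01"] <- NA
  co$features[c(2, 5), "code_003"] <- NA

  out <- impute_cohort(co)
  expect_false(anyNA(out$features))
  expect_equal(unname(out$features[1, "num_01"]),
               mean(co$features[-1, "num_01"]))
  obs <- co$features[-c(2, 5), "code_003"]
  expect_equal(unname(out$features[2, "code_003"]),
               as.numeric(names(which.max(table(obs)))))

  # hand example: numeric [1, NA, 3] -> mean 2; categorical [0,0,1,NA] -> 0
  toy <- structure(list(
    features = cbind(a = c(1, NA, 3, 2), b = c(0, 0, 1, NA)),
    labels = c(0L, 1L, 0L, 1L),
    feature_kinds = c("numeric", "categorical"),
    encounter_ids = paste0("e", 1:4)
  ), class = "encounter_matrix")
  out <- impute_cohort(toy)
  expect_equal(unname(out$features[2, "a"]), 2)
  expect_equal(unname(out$features[4, "b"]), 0)
})

test_that("imputation is idempotent, mean-preserving, and leaves observed cells", {
  co <- generate_cohort(cohort_spec(n_encounters = 200, missing_rate = 0.15,
                                    seed = 21))
  once <- impute_cohort(co)
  expect_identical(impute_cohort(once), once)

  obs <- !is.na(co$features)
  expect_equal(once$features[obs], co$features[obs])
  for (f in which(co$feature_kinds == "numeric")) {
    expect_equal(mean(once$features[, f]),
                 mean(co$features[, f], na.rm = TRUE))
  }
})

test_that("a fully missing feature is an error", {
  co <- generate_cohort(cohort_spec(n_encounters = 10, missing_rate = 0, seed = 3))
  co$features[, 5] <- NA
  expect_error(impute_cohort(co), "entirely missing")
})
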