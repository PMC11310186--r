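#' Specify a synthetic EHR cohort
#'
#' Describes an EHR-like cohort of hospital/ICU encounters with sparse binary
#' medical-code features, a few numeric features, latent cluster structure
#' (groups of clinically similar encounters), an imbalanced binary outcome,
#' and missing values. The defaults emulate the statistical shape of large
#' ICU cohorts: roughly 16 active codes per visit (diagnoses plus
#' treatments), 7--17% positive outcomes, and sporadic missingness.
#'
#' Each latent cluster owns a set of `codes_per_cluster` active codes drawn
#' without replacement from the code vocabulary, so distinct clusters have
#' low cosine overlap while members of the same cluster are highly similar.
#' Requires `n_clusters * codes_per_cluster <= n_code_features`.
#'
#' @param n_encounters number of encounters (graph nodes).
#' @param n_code_features size of the binary code vocabulary.
#' @param n_numeric_features number of numeric (standardised-scale) features.
#' @param n_clusters number of latent patient groups.
#' @param positive_rate target fraction of positive outcomes, in (0, 1).
#' @param cluster_outcome_strength probability that an encounter's label
#'   follows its cluster's dominant label (1 = labels determined by cluster,
#'   0 = labels independent of cluster), in \[0, 1\].
#' @param missing_rate per-cell probability of a missing value, in \[0, 1).
#' @param n_noise_flips number of random code bits flipped per encounter.
#' @param codes_per_cluster number of active codes in each cluster prototype.
#' @param seed integer RNG seed; the generator is deterministic given the spec.
#' @return an object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_encounters = 200, seed = 1)
#' cohort <- generate_cohort(spec)
#' table(cohort$labels)
cohort_spec <- function(n_encounters,
                        n_code_features = 200L,
                        n_numeric_features = 4L,
                        n_clusters = 10L,
                        positive_rate = 0.15,
                        cluster_outcome_strength = 0.8,
                        missing_rate = 0.05,
                        n_noise_flips = 2L,
                        codes_per_cluster = 16L,
                        seed = 1L) {
  spec <- structure(
    list(
      n_encounters = as.integer(n_encounters),
      n_code_features = as.integer(n_code_features),
      n_numeric_features = as.integer(n_numeric_features),
      n_clusters = as.integer(n_clusters),
      positive_rate = as.numeric(positive_rate),
      cluster_outcome_strength = as.numeric(cluster_outcome_strength),
      missing_rate = as.numeric(missing_rate),
      n_noise_flips = as.integer(n_noise_flips),
      codes_per_cluster = as.integer(codes_per_cluster),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

# 0/1-knapsack feasibility: indices of a subset of `sizes` whose sum is
# closest to `target` (deterministic; used to pick which clusters carry a
# positive dominant label).
closest_subset <- function(sizes, target) {
  total <- sum(sizes)
  reach <- c(TRUE, rep(FALSE, total))
  prev_cluster <- rep(NA_integer_, total + 1)
  prev_sum <- rep(NA_integer_, total + 1)
  for (g in seq_along(sizes)) {
    idx <- which(reach)
    cand <- idx + sizes[g]
    new <- cand[cand <= total + 1 & !reach[cand]]
    reach[new] <- TRUE
    prev_cluster[new] <- g
    prev_sum[new] <- new - sizes[g]
  }
  sums <- which(reach) - 1L
  best <- sums[which.min(abs(sums - target))]
  chosen <- integer(0)
  s <- best + 1L
  while (s > 1L) {
    chosen <- c(chosen, prev_cluster[s])
    s <- prev_sum[s]
  }
  chosen
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (is.na(n_encounters) || n_encounters < 1)
      stop_field("n_encounters", "must be a positive integer")
    if (is.na(n_code_features) || n_code_features < 1)
      stop_field("n_code_features", "must be a positive integer")
    if (is.na(n_numeric_features) || n_numeric_features < 0)
      stop_field("n_numeric_features", "must be a non-negative integer")
    if (is.na(n_clusters) || n_clusters < 1)
      stop_field("n_clusters", "must be a positive integer")
    if (n_clusters > n_encounters)
      stop_field("n_clusters", "cannot exceed n_encounters")
    if (!is.finite(positive_rate) || positive_rate <= 0 || positive_rate >= 1)
      stop_field("positive_rate", "must be strictly between 0 and 1")
    if (!is.finite(cluster_outcome_strength) ||
        cluster_outcome_strength < 0 || cluster_outcome_strength > 1)
      stop_field("cluster_outcome_strength", "must be in [0, 1]")
    if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 1)
      stop_field("missing_rate", "must be in [0, 1)")
    if (is.na(n_noise_flips) || n_noise_flips < 0)
      stop_field("n_noise_flips", "must be a non-negative integer")
    if (is.na(codes_per_cluster) || codes_per_cluster < 1)
      stop_field("codes_per_cluster", "must be a positive integer")
    if (as.double(n_clusters) * codes_per_cluster > n_code_features)
      stop_field("codes_per_cluster",
                 "n_clusters * codes_per_cluster must not exceed n_code_features (cluster prototypes are drawn without replacement)")
    if (is.na(seed)) stop_field("seed", "must be an integer")
  })
  invisible(spec)
}

#' Generate a synthetic EHR encounter matrix
#'
#' Draws each encounter from one of `n_clusters` sparse-code prototypes
#' (shared active-code set plus `n_noise_flips` random bit flips), adds
#' numeric features centred on cluster-specific means on a standardised
#' scale, assigns outcome labels correlated with cluster membership, and
#' inserts missing values (`NA`) at `missing_rate`. Deterministic given the
#' spec (including its seed).
#'
#' Cluster dominant labels are chosen by a largest-remainder-style greedy so
#' the expected positive fraction matches `positive_rate`; with
#' `cluster_outcome_strength = 1` every encounter inherits its cluster's
#' dominant label, with 0 labels are independent Bernoulli(`positive_rate`)
#' draws.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `encounter_matrix` with elements `features`
#'   (N x F numeric matrix, `NA` marks missing), `labels` (0/1 integer
#'   vector), `feature_kinds` (`"categorical"` for code indicators,
#'   `"numeric"` otherwise), `encounter_ids`, and `clusters` (the latent
#'   ground-truth assignment, for validation only — it is not a feature).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_encounters
  nc <- spec$n_code_features
  nn <- spec$n_numeric_features
  k <- spec$n_clusters

  with_local_seed(spec$seed, {
    # disjoint cluster prototypes over the code vocabulary
    vocab <- sample.int(nc)
    proto <- matrix(0L, nrow = k, ncol = nc)
    for (g in seq_len(k)) {
      active <- vocab[((g - 1) * spec$codes_per_cluster + 1):(g * spec$codes_per_cluster)]
      proto[g, active] <- 1L
    }
    cluster <- sample.int(k, n, replace = TRUE)

    codes <- proto[cluster, , drop = FALSE]
    if (spec$n_noise_flips > 0) {
      for (i in seq_len(n)) {
        pos <- sample.int(nc, spec$n_noise_flips)
        codes[i, pos] <- 1L - codes[i, pos]
      }
    }

    num <- NULL
    if (nn > 0) {
      centres <- matrix(stats::rnorm(k * nn, sd = 0.5), nrow = k)
      num <- centres[cluster, , drop = FALSE] +
        matrix(stats::rnorm(n * nn, sd = 0.3), nrow = n)
    }

    # dominant labels per cluster: exact subset-sum over cluster sizes so the
    # positive mass is as close to positive_rate as cluster granularity
    # allows (labels are constant per cluster when the strength dial is 1)
    sizes <- tabulate(cluster, nbins = k)
    dominant <- integer(k)
    dominant[closest_subset(sizes, round(n * spec$positive_rate))] <- 1L
    follows <- stats::runif(n) < spec$cluster_outcome_strength
    labels <- ifelse(follows, dominant[cluster],
                     stats::rbinom(n, 1L, spec$positive_rate))
    labels <- as.integer(labels)

    features <- cbind(codes, num)
    colnames(features) <- c(
      sprintf("code_%03d", seq_len(nc)),
      if (nn > 0) sprintf("num_%02d", seq_len(nn))
    )
    kinds <- c(rep("categorical", nc), rep("numeric", nn))

    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(n * (nc + nn)) < spec$missing_rate,
                     nrow = n)
      features[miss] <- NA_real_
    }

    structure(
      list(
        features = features,
        labels = labels,
        feature_kinds = kinds,
        encounter_ids = sprintf("enc%06d", seq_len(n)),
        clusters = cluster,
        spec = spec
      ),
      class = "encounter_matrix"
    )
  })
}

#' @export
print.encounter_matrix <- function(x, ...) {
  cat(sprintf(
    "<encounter_matrix> %d encounters x %d features (%d categorical, %d numeric)\n",
    nrow(x$features), ncol(x$features),
    sum(x$feature_kinds == "categorical"), sum(x$feature_kinds == "numeric")
  ))
  cat(sprintf("  positives: %d (%.1f%%); missing cells: %d\n",
              sum(x$labels), 100 * mean(x$labels), sum(is.na(x$features))))
  invisible(x)
}

#' Impute missing encounter features
#'
#' Missing entries of numeric features are replaced by the observed mean of
#' that feature; missing entries of categorical features (the binary code
#' indicators) by the observed mode. Observed entries are never changed, so
#' the operation is idempotent and preserves each numeric feature's observed
#' mean.
#'
#' @param cohort an `encounter_matrix`, possibly containing `NA` entries.
#' @return the cohort with `features` fully observed.
#' @export
impute_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "encounter_matrix"))
  x <- cohort$features
  for (f in seq_len(ncol(x))) {
    miss <- is.na(x[, f])
    if (!any(miss)) next
    obs <- x[!miss, f]
    if (length(obs) == 0)
      stop(sprintf("feature `%s` is entirely missing: no basis for imputation",
                   colnames(x)[f]), call. = FALSE)
    fill <- if (cohort$feature_kinds[f] == "numeric") {
      mean(obs)
    } else {
      # mode of observed values; ties broken by the smallest value
      tab <- table(obs)
      min(as.numeric(names(tab)[tab == max(tab)]))
    }
    x[miss, f] <- fill
  }
  cohort$features <- x
  cohort
}
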