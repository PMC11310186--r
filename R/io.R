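# Shared readers/writers. CSV dialect is fixed throughout: comma separator,
# UTF-8, "." decimal, no quoting of numerics, missing entries as an empty
# field. Doubles are rendered with "%.17g" so write -> read round-trips are
# bit-exact. Node indexing in all text formats (edge lists, cliques) is
# 0-based.

fmt_num <- function(v) {
  out <- ifelse(is.na(v), "",
                ifelse(v == floor(v) & abs(v) < 1e15,
                       sprintf("%.0f", v), sprintf("%.17g", v)))
  out
}

#' Write / read a cohort as delimited text
#'
#' The CSV has an `encounter_id` column, one column per feature, and a final
#' `label` column; missing entries are empty fields. A sidecar JSON
#' (`<path>.json`) records the generating [cohort_spec()] (when known) and
#' the feature kinds, so the reader can restore types exactly; without a
#' sidecar, integer-valued 0/1 columns are inferred as categorical.
#'
#' @param cohort an `encounter_matrix`.
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   an `encounter_matrix`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "encounter_matrix"))
  x <- cohort$features
  header <- paste(c("encounter_id", colnames(x), "label"), collapse = ",")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(cohort$encounter_ids[i], fmt_num(x[i, ]), cohort$labels[i]),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)

  sidecar <- list(
    feature_kinds = cohort$feature_kinds,
    feature_names = colnames(x)
  )
  if (!is.null(cohort$spec)) sidecar$spec <- unclass(cohort$spec)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("cohort file has no data rows", call. = FALSE)
  cols <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!"label" %in% cols)
    stop("cohort file lacks a 'label' column", call. = FALSE)

  # the final `label` field is never empty, so every row must split into
  # exactly length(cols) fields
  cells <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(cells) != length(cols))
  if (length(bad))
    stop(sprintf("ragged rows (wrong field count) at data row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  m <- do.call(rbind, cells)

  has_id <- cols[1] == "encounter_id"
  feat_cols <- setdiff(seq_along(cols), c(if (has_id) 1L, which(cols == "label")))
  feat_names <- cols[feat_cols]

  feat_chr <- m[, feat_cols, drop = FALSE]
  feat_chr[feat_chr == ""] <- NA_character_
  suppressWarnings(features <- matrix(as.numeric(feat_chr), nrow = nrow(m)))
  bad_num <- which(is.na(features) & !is.na(feat_chr), arr.ind = TRUE)
  if (nrow(bad_num) > 0)
    stop(sprintf("non-numeric value in feature column '%s' at data row %d",
                 feat_names[bad_num[1, 2]], bad_num[1, 1]), call. = FALSE)
  colnames(features) <- feat_names

  labels <- suppressWarnings(as.integer(m[, which(cols == "label")]))
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must all be 0 or 1", call. = FALSE)

  sidecar_path <- paste0(path, ".json")
  spec <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    kinds <- sc$feature_kinds
    if (!is.null(sc$spec))
      spec <- structure(as.list(sc$spec), class = "cohort_spec")
  } else {
    kinds <- apply(features, 2, function(v) {
      obs <- v[!is.na(v)]
      if (length(obs) && all(obs %in% c(0, 1))) "categorical" else "numeric"
    })
  }

  structure(
    list(
      features = features,
      labels = labels,
      feature_kinds = unname(kinds),
      encounter_ids = if (has_id) m[, 1] else sprintf("enc%06d", seq_len(nrow(m))),
      clusters = NULL,
      spec = spec
    ),
    class = "encounter_matrix"
  )
}

#' Export embeddings as CSV
#'
#' One row per encounter: `encounter_id` plus the embedding coordinates,
#' ready for downstream 2-D visualisation (t-SNE/UMAP) outside this package.
#'
#' @param embeddings N x F' matrix.
#' @param encounter_ids length-N identifiers.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_embeddings_csv <- function(embeddings, encounter_ids, path) {
  d <- ncol(embeddings)
  header <- paste(c("encounter_id", sprintf("dim_%02d", seq_len(d))),
                  collapse = ",")
  body <- vapply(seq_len(nrow(embeddings)), function(i) {
    paste(c(encounter_ids[i], fmt_num(embeddings[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Serialise / restore an encoder model as JSON
#'
#' Stores all parameters with their shapes, the init seed, and the hidden
#' dimension; portable plain text.
#'
#' @param model an [encoder_model()].
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` an
#'   `encoder_model`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    theta1 = model$theta1, theta2 = model$theta2,
    head_w = model$head_w, head_b = model$head_b,
    hidden_dim = model$hidden_dim, init_seed = model$init_seed
  )
  jsonlite::write_json(payload, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      theta1 = as.matrix(p$theta1), theta2 = as.matrix(p$theta2),
      head_w = as.numeric(p$head_w), head_b = as.numeric(p$head_b),
      hidden_dim = as.integer(p$hidden_dim), init_seed = as.integer(p$init_seed)
    ),
    class = "encoder_model"
  )
}

#' Build a run manifest
#'
#' Records the resolved configuration, package version, content digests of
#' the inputs, and start/end timestamps — enough to re-run or audit a
#' result directory.
#'
#' @param config the resolved configuration (any list-like object).
#' @param inputs named list of input objects or file paths to digest.
#' @param started,finished POSIXct timestamps.
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = list(),
                         started = Sys.time(), finished = Sys.time()) {
  digests <- lapply(inputs, function(obj) {
    if (is.character(obj) && length(obj) == 1 && file.exists(obj)) {
      rlang::hash(readLines(obj))
    } else {
      rlang::hash(obj)
    }
  })
  structure(
    list(
      config_echo = config,
      artifact_version = as.character(utils::packageVersion("psgnn")),
      input_digests = digests,
      timestamps = list(start = format(started, "%Y-%m-%dT%H:%M:%S%z"),
                        end = format(finished, "%Y-%m-%dT%H:%M:%S%z"))
    ),
    class = "run_manifest"
  )
}

#' Write a run's results, training log, and manifest
#'
#' Emits `results.json` (per-repeat and summary AUPRC), `training_log.jsonl`
#' (one JSON line per epoch per repeat with train/val losses and val AUPRC),
#' and `manifest.json` into `dir`. Files are written atomically (temp file +
#' rename), so re-running with the same config overwrites cleanly.
#'
#' @param result a `run_result` from [run_experiment()].
#' @param manifest a [run_manifest()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_results <- function(result, manifest, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  atomic_write <- function(write_fun, path) {
    tmp <- paste0(path, ".tmp")
    write_fun(tmp)
    file.rename(tmp, path)
    path
  }

  results_path <- atomic_write(function(p) {
    jsonlite::write_json(
      list(
        per_repeat_auprc = result$per_repeat_auprc,
        mean_auprc = result$mean_auprc,
        std_auprc = result$std_auprc,
        best_epoch = result$best_epoch,
        ablation = result$config$ablation,
        split_fractions = result$config$split_fractions
      ),
      p, auto_unbox = TRUE, digits = NA
    )
  }, file.path(dir, "results.json"))

  log_path <- atomic_write(function(p) {
    con <- file(p, open = "w")
    on.exit(close(con))
    for (r in seq_along(result$loss_history)) {
      h <- result$loss_history[[r]]
      for (e in seq_len(nrow(h))) {
        writeLines(jsonlite::toJSON(
          list(repeat_idx = r, epoch = h$epoch[e],
               train_loss = h$train_loss[e], val_loss = h$val_loss[e],
               val_auprc = h$val_auprc[e]),
          auto_unbox = TRUE, digits = NA
        ), con)
      }
    }
  }, file.path(dir, "training_log.jsonl"))

  manifest_path <- atomic_write(function(p) {
    jsonlite::write_json(unclass(manifest), p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }, file.path(dir, "manifest.json"))

  invisible(c(results = results_path, log = log_path, manifest = manifest_path))
}

#' Read back a written results file
#'
#' @param dir directory previously populated by [write_results()].
#' @return the parsed `results.json` as a list.
#' @export
read_results <- function(dir) {
  jsonlite::read_json(file.path(dir, "results.json"), simplifyVector = TRUE)
}
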