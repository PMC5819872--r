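#' Configuration of the bagged-tree ensemble
#'
#' The detector is an ensemble bagging classifier: `n_learners` unpruned
#' decision trees, each fitted on a bootstrap resample of the training
#' channels (with replacement, at full sample size), whose majority vote
#' classifies each channel. Bagging is used because bad channels are a rare
#' class (a few percent of contacts) and bootstrap aggregation copes with
#' that imbalance without explicit resampling; optional inverse-prevalence
#' class weighting is available but off by default.
#'
#' @param n_learners Number of trees (default 200).
#' @param seed RNG seed making training fully reproducible.
#' @param class_weighting `"none"` (default) or `"balanced"`
#'   (inverse-prevalence class priors).
#' @param tie_break Class assigned at a vote fraction of exactly 0.5
#'   (default `"bad"`: in quality control a false alarm is cheaper than a
#'   missed bad channel).
#' @return A `badchan_config` list.
#' @export
model_config <- function(n_learners = 200L, seed = 1L,
                         class_weighting = c("none", "balanced"),
                         tie_break = c("bad", "good")) {
  if (!is.numeric(n_learners) || n_learners < 1L) {
    abort("`n_learners` must be a positive integer.")
  }
  structure(
    list(
      n_learners = as.integer(n_learners),
      seed = as.integer(seed),
      class_weighting = match.arg(class_weighting),
      tie_break = match.arg(tie_break)
    ),
    class = "badchan_config"
  )
}

check_feature_table <- function(table, require_class = FALSE) {
  missing_cols <- setdiff(FEATURE_COLUMNS, names(table))
  if (length(missing_cols)) {
    abort(sprintf("Feature table lacks column(s): %s", toString(missing_cols)))
  }
  if (require_class && !"class" %in% names(table)) {
    abort("Training needs a `class` column (good/bad) in the feature table.")
  }
  if (anyNA(table[FEATURE_COLUMNS])) {
    abort("Feature table contains missing cells; degenerate channels should carry sentinel values, not NA.")
  }
  invisible(table)
}

#' Train the bad-channel detector
#'
#' Fits the bagged ensemble of [model_config()] on a labeled feature table
#' (the 7-features-plus-class contract of [extract_features()]). Rows are
#' put in a canonical order before the seeded bootstrap so the learned
#' model does not depend on how the caller ordered their channels. The
#' feature column order and the kurtosis/Hurst conventions of the training
#' table are stored in the model and enforced at prediction time.
#'
#' @param features Feature table with both classes present in `class`.
#' @param config A [model_config()].
#' @return A `badchan_model`.
#' @export
#' @examples
#' feats <- simulate_cohort_features(sim_config(n_shafts = 8,
#'     contacts_per_shaft = 5, baseline = 2, stim_duration = 2),
#'     n_subjects = 3, seed = 7)
#' fit <- train_detector(feats, model_config(n_learners = 25, seed = 1))
#' glance(fit)
train_detector <- function(features, config = model_config()) {
  stopifnot(inherits(config, "badchan_config"))
  check_feature_table(features, require_class = TRUE)
  classes <- unique(features$class)
  if (!all(classes %in% c("good", "bad"))) {
    abort(sprintf("Unknown class label(s): %s", toString(setdiff(classes, c("good", "bad")))))
  }
  if (length(classes) < 2L) {
    abort(paste(
      "Training table contains a single class;",
      "extend the dataset so both good and bad channels are represented."
    ))
  }

  x <- as.data.frame(features[FEATURE_COLUMNS])
  y <- factor(features$class, levels = c("good", "bad"))
  # canonical row order: decouple the seeded bootstrap from caller row order
  ord <- do.call(order, c(as.list(x), list(as.integer(y))))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]

  classwt <- NULL
  if (config$class_weighting == "balanced") {
    tab <- table(y)
    classwt <- as.numeric(sum(tab) / (2 * tab))
  }
  forest <- withr::with_seed(
    config$seed,
    randomForest::randomForest(
      x = x, y = y,
      ntree = config$n_learners,
      mtry = length(FEATURE_COLUMNS),  # all features: pure bagging, no feature subsampling
      nodesize = 1L, classwt = classwt
    )
  )

  conventions <- attr(features, "conventions", exact = TRUE) %||%
    list(kurtosis = "moment", hurst = "rs")
  structure(
    list(
      forest = forest,
      feature_order = FEATURE_COLUMNS,
      conventions = conventions,
      config = config,
      metadata = list(
        n_channels = nrow(features),
        prevalence_bad = mean(y == "bad"),
        seed = config$seed,
        package_version = as.character(packageVersion("badchan"))
      )
    ),
    class = "badchan_model"
  )
}

#' @export
print.badchan_model <- function(x, ...) {
  cat(sprintf(
    "<badchan_model> %d bagged trees, trained on %d channels (%.1f%% bad)\n",
    x$config$n_learners, x$metadata$n_channels, 100 * x$metadata$prevalence_bad
  ))
  cat("  features:", toString(x$feature_order), "\n")
  cat(sprintf("  conventions: kurtosis=%s, hurst=%s\n",
              x$conventions$kurtosis, x$conventions$hurst))
  invisible(x)
}

#' Predict good/bad channels from a feature table
#'
#' Applies the trained ensemble to new channels. Each tree votes; `vote_bad`
#' is the fraction of trees voting bad and `class` is the majority vote,
#' with an exact 0.5 tie resolved by the model's `tie_break` (default bad).
#' The table's feature columns and (when present) its kurtosis/Hurst
#' conventions must match the contract stored in the model.
#'
#' @param object A `badchan_model`.
#' @param features A feature table from [extract_features()].
#' @param ... Unused.
#' @return A tibble with `channel`, `label` (when present in `features`),
#'   `class` and `vote_bad`.
#' @export
predict.badchan_model <- function(object, features, ...) {
  check_feature_table(features)
  tab_conv <- attr(features, "conventions", exact = TRUE)
  if (!is.null(tab_conv) && !identical(tab_conv, object$conventions)) {
    abort(sprintf(
      "Feature conventions mismatch: model uses kurtosis=%s/hurst=%s, table was built with kurtosis=%s/hurst=%s.",
      object$conventions$kurtosis, object$conventions$hurst,
      tab_conv$kurtosis, tab_conv$hurst
    ), class = "badchan_contract_error")
  }
  x <- as.data.frame(features[object$feature_order])
  votes <- predict(object$forest, newdata = x, type = "vote", norm.votes = TRUE)
  vote_bad <- as.numeric(votes[, "bad"])
  threshold_hit <- if (object$config$tie_break == "bad") vote_bad >= 0.5 else vote_bad > 0.5
  out <- tibble::tibble(
    channel = if ("channel" %in% names(features)) features$channel else seq_len(nrow(features)),
    class = ifelse(threshold_hit, "bad", "good"),
    vote_bad = vote_bad
  )
  if ("label" %in% names(features)) {
    out <- dplyr::mutate(out, label = features$label, .after = "channel")
  }
  out
}

#' @export
tidy.badchan_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(
    feature = rownames(imp),
    importance = as.numeric(imp[, 1L])
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
glance.badchan_model <- function(x, ...) {
  conf <- x$forest$confusion
  tibble::tibble(
    n_learners = x$config$n_learners,
    n_channels = x$metadata$n_channels,
    prevalence_bad = x$metadata$prevalence_bad,
    oob_accuracy = sum(diag(conf[, 1:2])) / sum(conf[, 1:2]),
    seed = x$metadata$seed
  )
}

MODEL_VERSION <- 1L

#' Persist and restore a trained detector
#'
#' `save_model()` writes the ensemble to an RDS archive plus a JSON sidecar
#' (`<path>.json`) describing the contract: feature order, feature
#' conventions, seed and package version. `load_model()` restores the model
#' and refuses archives whose sidecar or stored contract is inconsistent,
#' naming the mismatch, so a model trained under one feature convention can
#' never be silently applied to tables built under another.
#'
#' @param model A `badchan_model`.
#' @param path File path for the archive.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `badchan_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "badchan_model"))
  obj <- unclass(model)
  obj$model_version <- MODEL_VERSION
  saveRDS(obj, path)
  jsonlite::write_json(
    list(
      kind = "badchan-model",
      model_version = MODEL_VERSION,
      feature_order = model$feature_order,
      conventions = model$conventions,
      n_learners = model$config$n_learners,
      seed = model$metadata$seed,
      package_version = model$metadata$package_version
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such model file: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$forest) || is.null(obj$model_version)) {
    abort(sprintf("File %s is not a badchan model archive.", path), class = "badchan_contract_error")
  }
  if (obj$model_version != MODEL_VERSION) {
    abort(sprintf(
      "Model version mismatch: archive has version %s, this package reads version %s.",
      obj$model_version, MODEL_VERSION
    ), class = "badchan_contract_error")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(as.character(meta$feature_order), obj$feature_order)) {
      abort(sprintf(
        "Feature-order mismatch between archive (%s) and sidecar (%s).",
        toString(obj$feature_order), toString(meta$feature_order)
      ), class = "badchan_contract_error")
    }
    if (!identical(as.character(meta$conventions$hurst), obj$conventions$hurst) ||
        !identical(as.character(meta$conventions$kurtosis), obj$conventions$kurtosis)) {
      abort("Feature-convention mismatch between archive and sidecar.", class = "badchan_contract_error")
    }
  }
  if (!identical(obj$feature_order, FEATURE_COLUMNS)) {
    abort(sprintf(
      "Model feature order (%s) does not match this package's contract (%s).",
      toString(obj$feature_order), toString(FEATURE_COLUMNS)
    ), class = "badchan_contract_error")
  }
  obj$model_version <- NULL
  structure(obj, class = "badchan_model")
}
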