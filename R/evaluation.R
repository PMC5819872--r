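#' Confusion counts for channel classification
#'
#' Counts channels with `bad` as the positive class: `tp` = bad labeled and
#' predicted bad, `tn` = good and predicted good, `fp` = good predicted
#' bad, `fn` = bad predicted good.
#'
#' @param truth,predicted Equal-length vectors over `c("good", "bad")`.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion(c("bad", "good", "good"), c("bad", "bad", "good"))
confusion <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort(sprintf("Label vectors differ in length (%d vs %d).",
                  length(truth), length(predicted)))
  }
  unknown <- setdiff(unique(c(truth, predicted)), c("good", "bad"))
  if (length(unknown)) {
    abort(sprintf("Unknown label(s): %s", toString(unknown)))
  }
  tibble::tibble(
    tp = sum(truth == "bad" & predicted == "bad"),
    tn = sum(truth == "good" & predicted == "good"),
    fp = sum(truth == "good" & predicted == "bad"),
    fn = sum(truth == "bad" & predicted == "good")
  )
}

#' Classification accuracy from confusion counts
#'
#' `(tp + tn) / (tp + fn + fp + tn)`, the fraction of channels whose
#' predicted class matches the expert label.
#'
#' @param counts A [confusion()] row (or any list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return Accuracy in `[0, 1]`.
#' @export
#' @examples
#' accuracy(confusion(rep("good", 9), rep("good", 9)))
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (any(c(counts$tp, counts$tn, counts$fp, counts$fn) < 0)) {
    abort("Confusion counts must be non-negative.")
  }
  if (total <= 0) abort("Cannot compute accuracy from zero evaluated channels.")
  (counts$tp + counts$tn) / total
}

split_subjects <- function(subjects, holdout_fraction, seed) {
  subjects <- sort(unique(subjects))
  n_hold <- round(holdout_fraction * length(subjects))
  held <- withr::with_seed(seed, sample(subjects, n_hold))
  list(held = sort(held), pool = setdiff(subjects, held))
}

#' Learning curve over training-set size
#'
#' Implements the training-size protocol: half of the cohort's subjects
#' (by default) are set aside once as a fixed held-out test set; for every
#' requested training size, `reps` random subsets of that many subjects are
#' drawn from the remaining pool, a detector is trained on their pooled
#' channels and its channel-level accuracy is measured on the held-out
#' channels. Splitting is always at the subject level, so no channel of a
#' test subject is ever seen in training. Each (size, repetition) pair gets
#' a child seed derived from the master seed.
#'
#' @param features A labeled cohort feature table
#'   ([simulate_cohort_features()] or equivalent) with `subject` and
#'   `class` columns.
#' @param sizes Strictly increasing training-set sizes, in subjects (the
#'   clinical protocol uses 10 to 200 in steps of 10).
#' @param reps Repetitions per size (protocol value 19).
#' @param holdout_fraction Fraction of subjects reserved for testing
#'   (default 0.5).
#' @param config Base [model_config()]; each repetition gets its derived
#'   seed.
#' @param seed Master seed for holdout and subset draws.
#' @return A `badchan_curve` tibble with columns `size`, `rep`, `seed`,
#'   `accuracy`; the held-out subjects are stored in the `holdout`
#'   attribute. Summarize with [glance()] and draw with [autoplot()].
#' @export
learning_curve <- function(features, sizes = seq(10L, 200L, by = 10L),
                           reps = 19L, holdout_fraction = 0.5,
                           config = model_config(), seed = 1L) {
  if (!"subject" %in% names(features) || !"class" %in% names(features)) {
    abort("`features` must carry `subject` and `class` columns.")
  }
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) abort("`sizes` must be strictly increasing.")
  sp <- split_subjects(features$subject, holdout_fraction, seed)
  if (max(sizes) > length(sp$pool)) {
    abort(sprintf(
      "Largest training size (%d subjects) exceeds the training pool (%d subjects after holding out %d).",
      max(sizes), length(sp$pool), length(sp$held)
    ))
  }
  test_tab <- dplyr::filter(features, .data$subject %in% sp$held)
  attr(test_tab, "conventions") <- attr(features, "conventions", exact = TRUE)

  grid <- tidyr::expand_grid(size = sizes, rep = seq_len(reps))
  grid$seed <- derive_seeds(seed, nrow(grid))
  grid$accuracy <- purrr::pmap_dbl(grid, function(size, rep, seed) {
    train_subj <- withr::with_seed(seed, sample(sp$pool, size))
    train_tab <- dplyr::filter(features, .data$subject %in% train_subj)
    attr(train_tab, "conventions") <- attr(features, "conventions", exact = TRUE)
    cfg <- config
    cfg$seed <- seed
    fit <- train_detector(train_tab, cfg)
    pred <- predict(fit, test_tab)
    accuracy(confusion(test_tab$class, pred$class))
  })
  class(grid) <- c("badchan_curve", class(grid))
  attr(grid, "holdout") <- sp$held
  attr(grid, "seed") <- seed
  grid
}

#' @export
glance.badchan_curve <- function(x, ...) {
  dplyr::summarise(
    tibble::as_tibble(x),
    n_reps = dplyr::n(),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = sd(.data$accuracy),
    min_accuracy = min(.data$accuracy),
    max_accuracy = max(.data$accuracy),
    .by = "size"
  )
}

#' @export
autoplot.badchan_curve <- function(object, ...) {
  s <- glance(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$size, y = 100 * .data$mean_accuracy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = 100 * (.data$mean_accuracy - .data$sd_accuracy),
        ymax = 100 * (.data$mean_accuracy + .data$sd_accuracy)
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Training-set size (subjects)",
      y = "Held-out channel accuracy (%)",
      title = "Bad-channel detection learning curve"
    ) +
    ggplot2::theme_minimal()
}

#' Per-group (per-center) accuracy of a trained detector
#'
#' Applies one trained model to every group of a cohort feature table and
#' reports channel-level confusion counts and accuracy per group, the
#' cross-center robustness check. The model must have been trained on
#' subjects disjoint from the evaluated table; empty groups are simply
#' absent from the result.
#'
#' @param model A `badchan_model`.
#' @param features A labeled cohort feature table with a `group` column.
#' @return A tibble with one row per group: `group`, `n_channels`, `tp`,
#'   `tn`, `fp`, `fn`, `accuracy`.
#' @export
grouped_accuracy <- function(model, features) {
  if (!"group" %in% names(features) || !"class" %in% names(features)) {
    abort("`features` must carry `group` and `class` columns.")
  }
  pred <- predict(model, features)
  dat <- dplyr::mutate(tibble::as_tibble(features), predicted = pred$class)
  dat |>
    dplyr::summarise(
      n_channels = dplyr::n(),
      tp = sum(.data$class == "bad" & .data$predicted == "bad"),
      tn = sum(.data$class == "good" & .data$predicted == "good"),
      fp = sum(.data$class == "good" & .data$predicted == "bad"),
      fn = sum(.data$class == "bad" & .data$predicted == "good"),
      .by = "group"
    ) |>
    dplyr::mutate(accuracy = (.data$tp + .data$tn) / .data$n_channels) |>
    dplyr::arrange(.data$group)
}

#' Per-feature discriminability t-tests (filter method)
#'
#' Ranks each of the seven features by how well it separates bad from good
#' channels on its own, independent of any classifier: a two-sample t-test
#' of the feature's values in the bad versus good class. The default is
#' Welch's unequal-variance test, since the bad class has grossly larger
#' spread by construction; the pooled-variance Student test is available
#' via `var_equal = TRUE`. No multiplicity correction is applied — this is
#' a filter-method ranking, not a family of confirmatory tests.
#'
#' @param features A labeled feature table (both classes present, at least
#'   two channels per class).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A tibble with `feature`, `statistic`, `p_value`, `mean_good`,
#'   `mean_bad`.
#' @export
feature_ttests <- function(features, var_equal = FALSE) {
  check_feature_table(features)
  if (!"class" %in% names(features)) abort("`features` must carry a `class` column.")
  if (length(unique(features$class)) < 2L) {
    abort("Both classes must be present for feature t-tests.")
  }
  if (min(table(features$class)) < 2L) {
    abort("Each class needs at least 2 channels.")
  }
  purrr::map_dfr(FEATURE_COLUMNS, function(f) {
    g <- features[[f]][features$class == "good"]
    b <- features[[f]][features$class == "bad"]
    if (var(g) == 0 && var(b) == 0) {
      abort(sprintf("Feature `%s` is constant in both classes; t-test undefined.", f))
    }
    tt <- t.test(b, g, var.equal = var_equal)
    tibble::tibble(
      feature = f,
      statistic = unname(tt$statistic),
      p_value = tt$p.value,
      mean_good = mean(g),
      mean_bad = mean(b)
    )
  })
}
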