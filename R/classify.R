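#' Stratified train/test split
#'
#' Randomly partitions cell records into training and test sets,
#' preserving per-class proportions (within rounding) when stratified.
#'
#' @param records A tibble with a `label` column.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param stratified Split within each label (default `TRUE`); requires
#'   at least 2 records per class.
#' @param seed Optional integer seed; the partition is reproducible for a
#'   fixed seed.
#' @return `records` with an added `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(records, train_fraction = 0.7,
                             stratified = TRUE, seed = NULL) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  if (train_fraction < 0 || train_fraction > 1) {
    abort("`train_fraction` must be in [0, 1]")
  }
  if (nrow(records) == 0) abort("`records` is empty")
  if (stratified) {
    sizes <- table(records$label)
    small <- names(sizes)[sizes < 2]
    if (length(small) > 0) {
      abort(sprintf("class(es) with fewer than 2 records under stratification: %s",
                    paste(small, collapse = ", ")))
    }
  }
  groups <- if (stratified) split(seq_len(nrow(records)), records$label) else
    list(seq_len(nrow(records)))
  train_idx <- with_seed_or_ambient(seed, {
    unlist(lapply(groups, function(ix) {
      ix[sample.int(length(ix), round(train_fraction * length(ix)))]
    }), use.names = FALSE)
  })
  split <- rep("test", nrow(records))
  split[train_idx] <- "train"
  if (train_fraction == 1) warn("`train_fraction` is 1: the test set is empty")
  records$split <- split
  records
}

#' Train a random-forest cell-line classifier
#'
#' Fits a random forest on the five integrin weight factors. Defaults
#' follow the conventional random-forest settings: 100 trees and
#' unlimited tree depth.
#'
#' @param train A tibble of training records with `label` and the five
#'   weight columns (rows with `split == "train"` are used when a
#'   `split` column is present).
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth; `NULL` (default) leaves depth
#'   unlimited.
#' @param seed Optional integer seed; predictions on a fixed probe set
#'   are reproducible for a fixed seed.
#' @param features Feature columns (default the five integrins).
#' @return A `sers_forest` model handle.
#' @export
train_forest <- function(train, n_trees = 100, max_depth = NULL,
                         seed = NULL, features = sers_integrins()) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  if ("split" %in% names(train)) {
    train <- train[train$split == "train", , drop = FALSE]
  }
  missing <- setdiff(features, names(train))
  if (length(missing) > 0) {
    abort(sprintf("training data is missing feature(s): %s",
                  paste(missing, collapse = ", ")))
  }
  y <- factor(train$label)
  if (nlevels(y) < 2) abort("training set must contain at least 2 classes")
  fit <- with_seed_or_ambient(seed, {
    randomForest::randomForest(
      x = as.data.frame(train[features]), y = y, ntree = n_trees,
      maxnodes = if (is.null(max_depth)) NULL else 2L^max_depth)
  })
  structure(list(fit = fit, features = features, levels = levels(y),
                 n_trees = n_trees, max_depth = max_depth, seed = seed),
            class = "sers_forest")
}

#' @export
print.sers_forest <- function(x, ...) {
  cat(sprintf("<sers_forest> %d trees, %s depth, classes: %s\n",
              x$n_trees,
              if (is.null(x$max_depth)) "unlimited" else x$max_depth,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
predict.sers_forest <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata is missing feature(s): %s",
                  paste(missing, collapse = ", ")))
  }
  # classify from the vote matrix with a fixed tie-break (first class in
  # level order) so prediction never consults the RNG
  votes <- predict(object$fit, as.data.frame(newdata[object$features]),
                   type = "vote", norm.votes = FALSE)
  factor(colnames(votes)[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `F1 = 2 * PRE * REC / (PRE + REC)`, defined as 0 when
#' both precision and recall are 0.
#'
#' @param pre,rec Precision and recall in \[0, 1\].
#' @return The F1 score.
#' @export
#' @examples
#' f1_from_pre_rec(0.8, 0.6)
f1_from_pre_rec <- function(pre, rec) {
  if (any(!is.finite(c(pre, rec))) || any(c(pre, rec) < 0) ||
      any(c(pre, rec) > 1)) {
    abort("`pre` and `rec` must lie in [0, 1]")
  }
  ifelse(pre + rec == 0, 0, 2 * pre * rec / (pre + rec))
}

#' Classification report from actual and predicted labels
#'
#' Builds the confusion matrix (counts and row-normalised fractions,
#' rows = actual, columns = predicted), per-class precision, recall and
#' F1, the macro-averaged F1 (unweighted mean over classes) and overall
#' accuracy.
#'
#' @param actual,predicted Label vectors of equal length.
#' @param levels Class levels (default: union of observed labels).
#' @return A `classifier_report`.
#' @export
classification_report <- function(actual, predicted,
                                  levels = sort(unique(c(as.character(actual),
                                                         as.character(predicted))))) {
  actual <- factor(as.character(actual), levels = levels)
  predicted <- factor(as.character(predicted), levels = levels)
  if (anyNA(actual) || anyNA(predicted)) abort("labels outside `levels`")
  counts <- table(actual = actual, predicted = predicted)
  row_tot <- rowSums(counts)
  fractions <- counts / ifelse(row_tot == 0, 1, row_tot)
  per_class <- purrr::map_dfr(levels, function(cl) {
    tp <- counts[cl, cl]
    col_tot <- sum(counts[, cl])
    pre <- if (col_tot > 0) tp / col_tot else 0
    rec <- if (row_tot[[cl]] > 0) tp / row_tot[[cl]] else 0
    tibble::tibble(class = cl, n = unname(row_tot[[cl]]),
                   precision = pre, recall = rec,
                   f1 = f1_from_pre_rec(pre, rec))
  })
  structure(list(confusion_counts = unclass(counts),
                 confusion_fractions = unclass(fractions),
                 per_class = per_class,
                 macro_f1 = mean(per_class$f1),
                 accuracy = sum(diag(counts)) / sum(counts),
                 n = sum(counts)),
            class = "classifier_report")
}

#' Evaluate a fitted classifier on held-out records
#'
#' @param model A `sers_forest`.
#' @param test A tibble of labelled records (rows with `split == "test"`
#'   are used when a `split` column is present).
#' @return A `classifier_report`; see [classification_report()].
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "sers_forest"),
            is.data.frame(test), "label" %in% names(test))
  if ("split" %in% names(test)) test <- test[test$split == "test", , drop = FALSE]
  if (nrow(test) == 0) abort("test set is empty")
  unknown <- setdiff(unique(test$label), model$levels)
  if (length(unknown) > 0) {
    abort(sprintf("unknown label(s) in test set: %s",
                  paste(unknown, collapse = ", ")))
  }
  classification_report(test$label, predict(model, test),
                        levels = model$levels)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> n = %d, accuracy = %.4f, macro F1 = %.4f\n",
              x$n, x$accuracy, x$macro_f1))
  print(round(x$confusion_fractions, 3))
  invisible(x)
}

#' @rdname classification_report
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @exportS3Method
tidy.classifier_report <- function(x, ...) x$per_class

#' @rdname classification_report
#' @exportS3Method
glance.classifier_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1, n = x$n)
}

#' @exportS3Method
autoplot.classifier_report <- function(object, ...) {
  d <- as.data.frame(as.table(object$confusion_fractions))
  names(d) <- c("actual", "predicted", "fraction")
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$actual,
                                  fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fraction))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted", y = "Actual", fill = "Fraction")
}

#' Repeated stratified training protocol
#'
#' Runs `n_iterations` independent stratified train/test resplits of the
#' records, fitting and evaluating a fresh forest each time with its own
#' derived seed, and averages the macro F1 (and accuracy) across
#' iterations.
#'
#' @param records Labelled records with the five weight columns.
#' @param n_iterations Number of resplit/fit/evaluate iterations
#'   (default 200).
#' @param train_fraction Passed to [split_train_test()] (default 0.7).
#' @param n_trees,max_depth Passed to [train_forest()].
#' @param seed Optional top-level seed; the whole protocol is
#'   deterministic under a fixed seed.
#' @return A `training_protocol`: per-iteration scores, their means, and
#'   the retained per-iteration reports.
#' @export
repeat_training <- function(records, n_iterations = 200, train_fraction = 0.7,
                            n_trees = 100, max_depth = NULL, seed = NULL) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  seeds <- matrix(derive_seeds(seed, 2L * n_iterations), ncol = 2)
  reports <- purrr::map(seq_len(n_iterations), function(i) {
    parts <- split_train_test(records, train_fraction, stratified = TRUE,
                              seed = seeds[i, 1])
    model <- train_forest(parts, n_trees = n_trees, max_depth = max_depth,
                          seed = seeds[i, 2])
    evaluate_classifier(model, parts)
  })
  summary <- purrr::map_dfr(seq_along(reports), function(i) {
    tibble::tibble(iteration = i, split_seed = seeds[i, 1],
                   fit_seed = seeds[i, 2],
                   macro_f1 = reports[[i]]$macro_f1,
                   accuracy = reports[[i]]$accuracy)
  })
  structure(list(summary = summary,
                 mean_macro_f1 = mean(summary$macro_f1),
                 mean_accuracy = mean(summary$accuracy),
                 n_iterations = n_iterations, seed = seed,
                 reports = reports),
            class = "training_protocol")
}

#' @export
print.training_protocol <- function(x, ...) {
  cat(sprintf(
    "<training_protocol> %d iterations, mean macro F1 = %.4f, mean accuracy = %.4f\n",
    x$n_iterations, x$mean_macro_f1, x$mean_accuracy))
  invisible(x)
}

#' @rdname repeat_training
#' @param x A `training_protocol`.
#' @param ... Unused.
#' @exportS3Method
tidy.training_protocol <- function(x, ...) x$summary

#' @rdname repeat_training
#' @exportS3Method
glance.training_protocol <- function(x, ...) {
  tibble::tibble(mean_macro_f1 = x$mean_macro_f1,
                 mean_accuracy = x$mean_accuracy,
                 n_iterations = x$n_iterations)
}

#' Predict the composition of an unlabelled population
#'
#' Applies a fitted classifier to each cell of a mixed population and
#' summarises predicted class counts and per-class mean weight profiles.
#'
#' @param model A `sers_forest`.
#' @param records Unlabelled records with the model's feature columns
#'   (any `label` column is ignored).
#' @return A `prediction_summary`: per-cell predictions, class counts
#'   (summing to the number of cells) and per-class mean profiles.
#' @export
predict_population <- function(model, records) {
  stopifnot(inherits(model, "sers_forest"), is.data.frame(records))
  if (nrow(records) == 0) abort("`records` is empty")
  pred <- predict(model, records)
  counts <- table(factor(pred, levels = model$levels))
  cells <- tibble::tibble(
    cell_id = if ("cell_id" %in% names(records)) records$cell_id else
      as.character(seq_len(nrow(records))),
    predicted = as.character(pred))
  profiles <- dplyr::bind_cols(cells["predicted"],
                               records[model$features]) |>
    dplyr::group_by(.data$predicted) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop")
  structure(list(cells = cells,
                 counts = setNames(as.integer(counts), names(counts)),
                 n_total = nrow(records),
                 mean_profiles = profiles),
            class = "prediction_summary")
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat(sprintf("<prediction_summary> %d cells: %s\n", x$n_total,
              paste(sprintf("%s = %d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname predict_population
#' @param x A `prediction_summary`.
#' @param ... Unused.
#' @exportS3Method
tidy.prediction_summary <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(predicted = names(x$counts),
                   count = unname(x$counts)),
    x$mean_profiles, by = "predicted")
}

#' @rdname predict_population
#' @exportS3Method
glance.prediction_summary <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_classes = length(x$counts))
}

#' Correlate predicted-population profiles with training profiles
#'
#' Pools the per-class mean weight of every (class, marker) pair from a
#' predicted mixed population and from the labelled training data, and
#' correlates the two with [pearson_with_slope_p()].
#'
#' @param prediction A `prediction_summary`.
#' @param training Labelled training records.
#' @param features Marker columns (default the five integrins).
#' @return A `correlation_result` over all (class, marker) pairs.
#' @export
profile_correlation <- function(prediction, training,
                                features = sers_integrins()) {
  stopifnot(inherits(prediction, "prediction_summary"),
            "label" %in% names(training))
  train_means <- training |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(features), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"label", names_to = "marker",
                        values_to = "train_mean")
  pred_means <- prediction$mean_profiles |>
    tidyr::pivot_longer(-"predicted", names_to = "marker",
                        values_to = "predicted_mean") |>
    dplyr::rename(label = "predicted")
  joined <- dplyr::inner_join(train_means, pred_means,
                              by = c("label", "marker"))
  pearson_with_slope_p(joined$train_mean, joined$predicted_mean)
}
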