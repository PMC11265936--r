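#' Confusion counts for a binary classification
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive The label counted as positive.
#' @return An object of class `confusion_counts` with fields `tp, tn, fp,
#'   fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = "male") {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    abort_validation("y_true and y_pred must be equal-length, nonempty")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  labels <- union(unique(y_true), unique(y_pred))
  if (length(labels) > 2L)
    abort_validation("labels must be binary")
  if (!positive %in% labels)
    abort_validation(sprintf("positive label '%s' not present", positive))
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  structure(list(tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
                 fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p),
                 positive = positive),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (positive = %s): TP=%d TN=%d FP=%d FN=%d\n",
              x$positive, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' `F1 = 2 * precision * recall / (precision + recall)`.
#'
#' @param precision,recall Values in \[0, 1\] with a positive sum.
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (!is_scalar_num(precision) || !is_scalar_num(recall) ||
      precision < 0 || precision > 1 || recall < 0 || recall > 1)
    abort_validation("precision and recall must lie in [0, 1]")
  if (precision + recall <= 0)
    abort_undefined("F1 undefined: precision + recall is zero")
  2 * precision * recall / (precision + recall)
}

#' Classification metrics from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `balanced accuracy = (sensitivity +
#' specificity) / 2`, and F1 as in [f1_score()]. A zero denominator makes
#' the affected metric undefined: by default this raises a classed error;
#' `undefined = "nan"` instead records `NaN` for the affected metrics.
#'
#' @param counts A [confusion_counts].
#' @param undefined `"error"` (default) or `"nan"`.
#' @return An object of class `classification_metrics` with fields
#'   `precision, recall, specificity, balanced_accuracy, f1`.
#' @export
compute_metrics <- function(counts, undefined = c("error", "nan")) {
  undefined <- match.arg(undefined)
  if (!inherits(counts, "confusion_counts"))
    abort_validation("counts must be confusion_counts")
  ratio <- function(num, den, what) {
    if (den == 0) {
      if (undefined == "error") abort_undefined(sprintf("%s undefined: zero denominator", what))
      return(NaN)
    }
    num / den
  }
  with(counts, {
    recall <- ratio(tp, tp + fn, "recall/sensitivity")
    specificity <- ratio(tn, tn + fp, "specificity")
    precision <- ratio(tp, tp + fp, "precision")
    ba <- (recall + specificity) / 2
    f1 <- if (is.nan(precision) || is.nan(recall)) NaN
          else if (precision + recall == 0) {
            if (undefined == "error") abort_undefined("F1 undefined: precision + recall is zero")
            NaN
          } else 2 * precision * recall / (precision + recall)
    structure(list(precision = precision, recall = recall,
                   specificity = specificity, balanced_accuracy = ba,
                   f1 = f1),
              class = "classification_metrics")
  })
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("BA=%.3f  P=%.3f  R=%.3f  Spec=%.3f  F1=%.3f\n",
              x$balanced_accuracy, x$precision, x$recall, x$specificity,
              x$f1))
  invisible(x)
}

#' Random oversampling of the minority class
#'
#' Appends minority rows resampled with replacement until class counts are
#' equal; every original row is retained. An already balanced input is
#' returned unchanged.
#'
#' @param rows A data frame of feature rows with a `sex` column.
#' @param label_col Name of the class column.
#' @param seed Integer RNG seed.
#' @return The balanced data frame (originals first).
#' @export
random_oversample <- function(rows, label_col = "sex", seed = 1) {
  if (!is.data.frame(rows) || !label_col %in% names(rows))
    abort_validation(sprintf("rows must be a data frame with a '%s' column", label_col))
  counts <- table(rows[[label_col]])
  if (length(counts) < 2L) abort_validation("both classes must be present")
  n_add <- max(counts) - min(counts)
  if (n_add == 0L) return(rows)
  minority <- names(counts)[which.min(counts)]
  idx_min <- which(rows[[label_col]] == minority)
  extra <- with_seed(seed, sample(idx_min, n_add, replace = TRUE))
  out <- rbind(rows, rows[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Cross-validation and grid-search specification
#'
#' Stratified 3-fold cross-validation on the training rows, selecting the
#' random-forest hyperparameters (number of trees, maximum tree depth,
#' features considered per split) that maximize balanced accuracy.
#'
#' @param n_folds Number of stratified folds (default 3).
#' @param grid Data frame of hyperparameter combinations with columns
#'   `ntree`, `max_depth` (`NA` = unlimited) and `mtry_mode` (`"all"` or
#'   `"sqrt"`).
#' @param seed Integer RNG seed for fold assignment and forest fits.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 3, grid = default_rf_grid(), seed = 1) {
  if (!is_scalar_num(n_folds) || n_folds < 2) abort_validation("n_folds must be >= 2")
  if (!is.data.frame(grid) || nrow(grid) == 0L ||
      !all(c("ntree", "max_depth", "mtry_mode") %in% names(grid)))
    abort_validation("grid must be a nonempty data frame with ntree, max_depth, mtry_mode")
  structure(list(n_folds = as.integer(n_folds), grid = grid,
                 seed = as.integer(seed)), class = "cv_spec")
}

#' @rdname cv_spec
#' @export
default_rf_grid <- function() {
  expand.grid(ntree = c(100, 300), max_depth = c(NA, 5, 10),
              mtry_mode = c("all", "sqrt"), stringsAsFactors = FALSE)
}

# Per-class shuffled fold assignment; every fold keeps both classes when
# each class has >= n_folds members.
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

rf_fit <- function(x, y, ntree, max_depth, mtry_mode, seed) {
  mtry <- if (mtry_mode == "sqrt") max(1L, floor(sqrt(ncol(x)))) else ncol(x)
  # cap at the number of cases: a tree cannot have more leaves than samples
  maxnodes <- if (is.na(max_depth)) NULL
              else min(2L^as.integer(max_depth), nrow(x))
  with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                               maxnodes = maxnodes))
}

#' Grid-searched random forest with evaluation on a held-out test set
#'
#' Runs the full classifier protocol: stratified k-fold cross-validated
#' grid search (selection metric: balanced accuracy) over random-forest
#' hyperparameters on the training rows, refit of the best configuration on
#' all training rows, and metric computation on the untouched test rows
#' with the minority class as positive. Undefined test metrics (e.g. no
#' positive predictions) are reported as `NaN` rather than aborting, but a
#' single-class test set is an error because balanced accuracy is undefined
#' there.
#'
#' @param train_rows,test_rows Feature data frames with a `sex` column;
#'   `test_rows` must be real records only.
#' @param features Character vector of feature column names.
#' @param cv A [cv_spec].
#' @param positive Positive class label (default `"male"`).
#' @return A list of class `rf_evaluation`: `model` (the refit forest),
#'   `metrics` ([compute_metrics()] output), `counts`, `best` (selected
#'   grid row), `cv_table` (mean CV balanced accuracy per grid row).
#' @export
fit_and_evaluate <- function(train_rows, test_rows, features,
                             cv = cv_spec(), positive = "male") {
  for (df in list(train_rows, test_rows))
    if (!is.data.frame(df) || !all(c(features, "sex") %in% names(df)))
      abort_validation("rows must contain the feature columns and 'sex'")
  if ("provenance" %in% names(test_rows) && any(test_rows$provenance != "real"))
    abort_validation("test rows must be real records only")
  if (length(unique(test_rows$sex)) < 2L)
    abort_undefined("balanced accuracy undefined: single-class test set")
  if (anyNA(train_rows[, features]) || anyNA(test_rows[, features]))
    abort_validation("feature columns contain missing values")
  y_train <- factor(train_rows$sex, levels = gan_classes)
  x_train <- as.matrix(train_rows[, features, drop = FALSE])
  fold <- stratified_folds(train_rows$sex, cv$n_folds,
                           child_seed(cv$seed, "folds"))
  cv_ba <- numeric(nrow(cv$grid))
  for (gi in seq_len(nrow(cv$grid))) {
    g <- cv$grid[gi, ]
    bas <- numeric(cv$n_folds)
    for (f in seq_len(cv$n_folds)) {
      tr <- fold != f; te <- fold == f
      fit <- rf_fit(x_train[tr, , drop = FALSE], droplevels(y_train[tr]),
                    g$ntree, g$max_depth, g$mtry_mode,
                    child_seed(cv$seed, sprintf("rf_%d_%d", gi, f)))
      pred <- as.character(stats::predict(fit, x_train[te, , drop = FALSE]))
      met <- compute_metrics(
        confusion_counts(as.character(y_train[te]), pred, positive),
        undefined = "nan")
      bas[f] <- met$balanced_accuracy
    }
    cv_ba[gi] <- mean(bas, na.rm = TRUE)
  }
  best_i <- which.max(cv_ba)               # ties -> first (deterministic)
  g <- cv$grid[best_i, ]
  model <- rf_fit(x_train, y_train, g$ntree, g$max_depth, g$mtry_mode,
                  child_seed(cv$seed, "rf_final"))
  pred <- as.character(stats::predict(
    model, as.matrix(test_rows[, features, drop = FALSE])))
  counts <- confusion_counts(test_rows$sex, pred, positive)
  metrics <- compute_metrics(counts, undefined = "nan")
  structure(list(model = model, metrics = metrics, counts = counts,
                 best = g, cv_table = cbind(cv$grid, cv_ba = cv_ba),
                 features = features, positive = positive),
            class = "rf_evaluation")
}

#' @export
print.rf_evaluation <- function(x, ...) {
  cat(sprintf("Random forest (%s; positive = %s)\n",
              paste(x$features, collapse = ", "), x$positive))
  cat(sprintf("  selected: ntree=%d, max_depth=%s, mtry=%s\n",
              x$best$ntree, ifelse(is.na(x$best$max_depth), "unlimited",
                                   x$best$max_depth), x$best$mtry_mode))
  cat("  test: "); print(x$metrics)
  invisible(x)
}

#' Evaluate the three training conditions on one untouched test set
#'
#' Reproduces the study's comparison for a single stimulus: a classifier is
#' trained on (a) the original imbalanced training rows, (b) the randomly
#' oversampled rows, and (c) the training set augmented with GAN-generated
#' minority waveforms (low-pass smoothed, then feature-extracted), and all
#' three are evaluated on the same real, unbalanced test rows. The test
#' rows are hashed once and the hash recorded per condition, proving
#' test-set immutability.
#'
#' @param real_train,test [erg_dataset]s of one stimulus; `test` real-only.
#' @param generator A fitted [erg_cgan] for the same stimulus (may be
#'   `NULL` to skip the synthesized condition).
#' @param policy An [augmentation_policy].
#' @param cv A [cv_spec].
#' @param lowpass A [lowpass_spec] applied to synthetic records.
#' @param initial_size The pre-split dataset size the fraction policy
#'   refers to; defaults to `length(real_train) + length(test)`.
#' @param seed Integer RNG seed (oversampling and latent draws).
#' @param ... Feature-extraction arguments (windows, `lb_mode`).
#' @return An object of class `condition_report`: a data frame with one row
#'   per condition (`condition, ba, precision, recall, f1`) plus metadata
#'   attributes (`test_hash`, per-condition train sizes, exclusion logs).
#' @export
run_conditions <- function(real_train, test, generator = NULL,
                           policy = augmentation_policy(), cv = cv_spec(),
                           lowpass = lowpass_spec(),
                           initial_size = length(real_train) + length(test),
                           seed = 1, ...) {
  for (d in list(real_train, test))
    if (!inherits(d, "erg_dataset") || length(d) == 0L)
      abort_validation("real_train and test must be nonempty erg_datasets")
  mtr <- waveform_meta(real_train); mte <- waveform_meta(test)
  st <- unique(c(mtr$stimulus, mte$stimulus))
  if (length(st) != 1L) abort_validation("run_conditions handles one stimulus at a time")
  if (any(mte$provenance != "real")) abort_validation("test set must be real records only")
  feats <- stimulus_features(st)

  train_rows <- feature_table(real_train, ..., quiet = TRUE)
  test_rows <- feature_table(test, ..., quiet = TRUE)
  test_hash <- hash_table(test_rows[, c("subject_id", "eye", "sex",
                                        "replicate_index", feats)])

  conditions <- list(original = train_rows,
                     oversampled = random_oversample(
                       train_rows, seed = child_seed(seed, "oversample")))
  excl <- list(original = attr(train_rows, "exclusions"),
               test = attr(test_rows, "exclusions"))
  if (!is.null(generator)) {
    aug <- balance_with_synthetic(real_train, generator, policy,
                                  seed = child_seed(seed, "generate"),
                                  initial_size = initial_size)
    aug <- lowpass_dataset(aug, lowpass, provenance_only = "synthetic")
    synth_rows <- feature_table(subset_dataset(aug, provenance = "synthetic"),
                                ..., quiet = TRUE)
    excl$synthesized <- attr(synth_rows, "exclusions")
    conditions$synthesized <- rbind(train_rows, synth_rows)
  }

  rows <- list(); evals <- list()
  for (cond in names(conditions)) {
    ev <- fit_and_evaluate(conditions[[cond]], test_rows, feats,
                           cv = cv, positive = policy$target_class)
    evals[[cond]] <- ev
    rows[[cond]] <- data.frame(
      stimulus = st, condition = cond,
      ba = ev$metrics$balanced_accuracy, precision = ev$metrics$precision,
      recall = ev$metrics$recall, f1 = ev$metrics$f1,
      n_train = nrow(conditions[[cond]]), n_test = nrow(test_rows),
      test_hash = test_hash, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  structure(out, class = c("condition_report", "data.frame"),
            evaluations = evals, exclusions = excl, test_hash = test_hash)
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("Condition report (%s; test n=%d, hash %s)\n",
              paste(unique(x$stimulus), collapse = "+"), x$n_test[1],
              substr(x$test_hash[1], 1, 8)))
  df <- as.data.frame(x)[, c("stimulus", "condition", "ba", "precision",
                             "recall", "f1", "n_train")]
  df[, 3:6] <- round(df[, 3:6], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a condition report as CSV and JSON
#'
#' One CSV per stimulus mirroring the study's table layout
#' (`dataset_analysis, ba, precision, recall, f1`) plus a JSON file with
#' full provenance (seeds, configuration echo, test-set hash).
#'
#' @param report A `condition_report` (or the report of an experiment).
#' @param dir Output directory (created if needed).
#' @param meta Optional named list embedded in the JSON (config echo,
#'   seeds).
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  df <- as.data.frame(report)
  for (st in unique(df$stimulus)) {
    sub <- df[df$stimulus == st, ]
    csv <- data.frame(dataset_analysis = sub$condition, ba = sub$ba,
                      precision = sub$precision, recall = sub$recall,
                      f1 = sub$f1)
    p <- file.path(dir, sprintf("report_%s.csv", st))
    utils::write.csv(csv, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  j <- file.path(dir, "report.json")
  jsonlite::write_json(c(list(report = df), meta), j, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, j))
}
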