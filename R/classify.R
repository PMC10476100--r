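# Six-stage ripeness classification with classical learners.
#
# Four families are supported, each with the tuned defaults reported for
# this task: multinomial L2 logistic regression (c = 0.7), k-nearest
# neighbours (12 neighbours), random forest (35 trees, depth 20) and an RBF
# support-vector machine (C = 10, gamma = 5e-4). Features are regional
# channel means on the 0-255 scale and are deliberately NOT standardized:
# the SVM gamma is calibrated for raw 8-bit magnitudes and rescaling would
# invalidate it.

#' Describe a classifier family and its hyperparameters
#'
#' @param family One of `"svm"`, `"lr"`, `"knn"`, `"rf"`.
#' @param params Named list of hyperparameters; unset entries take the tuned
#'   defaults: LR `c = 0.7` (inverse L2 penalty), KNN `n_neighbors = 12`,
#'   RF `n_estimators = 35, max_depth = 20`, SVM `C = 10, gamma = 5e-4`
#'   with an RBF kernel.
#' @param grid Named list of candidate values for [tune_ripeness()]; `NULL`
#'   uses the bundled default grid bracketing the defaults.
#' @return A `classifier_spec`.
#' @examples
#' classifier_spec("svm")
#' classifier_spec("knn", params = list(n_neighbors = 5))
#' @export
classifier_spec <- function(family = c("svm", "lr", "knn", "rf"),
                            params = list(), grid = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    lr = list(c = 0.7),
    knn = list(n_neighbors = 12),
    rf = list(max_depth = 20, n_estimators = 35),
    svm = list(C = 10, kernel = "rbf", gamma = 5e-4)
  )
  params <- utils::modifyList(defaults, params)
  structure(list(family = family, params = params, grid = grid),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s: %s\n", toupper(x$family),
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  if (!is.null(x$cv_results)) {
    cat(sprintf("  tuned by %d-point grid search; best CV accuracy %.3f\n",
                nrow(x$cv_results), max(x$cv_results$mean_accuracy)))
  }
  invisible(x)
}

default_grid <- function(family) {
  switch(family,
    svm = list(C = c(0.1, 1, 10, 100), gamma = c(5e-5, 5e-4, 5e-3)),
    knn = list(n_neighbors = 4:20),
    rf = list(n_estimators = c(15, 25, 35, 50), max_depth = c(10, 20, 30)),
    lr = list(c = c(0.1, 0.4, 0.7, 1.0))
  )
}

# Keys that define "simpler" (ascending) for tie-breaking in grid search.
complexity_keys <- function(family) {
  switch(family,
    svm = c("C", "gamma"), knn = "n_neighbors",
    rf = c("n_estimators", "max_depth"), lr = "c"
  )
}

split_features <- function(data, label_col = "label") {
  drop <- intersect(c(label_col, "instance_id"), names(data))
  x <- as.matrix(data[, setdiff(names(data), drop), drop = FALSE])
  if (!is.numeric(x)) stopf("berry_bad_features", "feature columns must be numeric")
  if (!all(is.finite(x))) stopf("berry_bad_features", "features contain non-finite values")
  y <- NULL
  if (label_col %in% names(data)) {
    y <- data[[label_col]]
    if (!is.factor(y)) y <- factor(y)
  }
  list(x = x, y = y)
}

#' Fit a ripeness classifier
#'
#' @param data Feature tibble from [extract_features()] (or any data frame of
#'   numeric features): one row per instance, a `label` column, optionally an
#'   `instance_id` column (ignored as a feature).
#' @param spec A [classifier_spec()]; a family name string is also accepted.
#' @param label_col Name of the label column.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @return A `ripeness_model` storing the fitted backend, the feature schema
#'   (checked again at prediction time) and the class levels.
#' @examples
#' \donttest{
#' feats <- synth_dataset(10, seed = 1) |> extract_features()
#' model <- fit_ripeness(feats, classifier_spec("svm"), seed = 0)
#' }
#' @export
fit_ripeness <- function(data, spec = classifier_spec("svm"),
                         label_col = "label", seed = 0) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  fy <- split_features(data, label_col)
  if (is.null(fy$y)) stopf("berry_bad_features", "no `%s` column in data", label_col)
  y <- droplevels(fy$y)
  if (nlevels(y) < 2) {
    stopf("berry_single_class", "training data contains a single class")
  }
  x <- fy$x
  p <- spec$params
  fit <- with_seed(seed, switch(spec$family,
    svm = e1071::svm(x, y, type = "C-classification", kernel = "radial",
                     cost = p$C, gamma = p$gamma, probability = TRUE,
                     scale = FALSE),
    knn = caret::knn3(x, y, k = p$n_neighbors),
    rf = ranger::ranger(x = x, y = y, num.trees = p$n_estimators,
                        max.depth = p$max_depth, probability = TRUE,
                        seed = seed, num.threads = 1),
    lr = glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = 1 / (p$c * nrow(x)), standardize = FALSE)
  ))
  structure(list(family = spec$family, params = p, schema = colnames(x),
                 levels = levels(y), fit = fit, seed = seed),
            class = "ripeness_model")
}

#' @export
print.ripeness_model <- function(x, ...) {
  cat(sprintf("<ripeness_model> %s on %d features; classes: %s\n",
              toupper(x$family), length(x$schema),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

check_schema <- function(model, data) {
  missing <- setdiff(model$schema, names(data))
  if (length(missing)) {
    stopf("berry_schema_mismatch", "newdata lacks feature column(s): %s",
          paste(head(missing, 5), collapse = ", "))
  }
  as.matrix(data[, model$schema, drop = FALSE])
}

#' Per-class prediction probabilities
#'
#' @param model A `ripeness_model`.
#' @param data Feature table with at least the model's schema columns.
#' @return A numeric matrix, one row per instance, one column per class
#'   (model level order); rows sum to 1. SVM probabilities come from
#'   pairwise-coupled sigmoid calibration fitted during training.
#' @export
predict_proba <- function(model, data) {
  x <- check_schema(model, data)
  lev <- model$levels
  pr <- switch(model$family,
    svm = {
      p <- predict(model$fit, x, probability = TRUE)
      attr(p, "probabilities")
    },
    knn = predict(model$fit, x, type = "prob"),
    rf = predict(model$fit, data = data.frame(x, check.names = FALSE),
                 num.threads = 1)$predictions,
    lr = predict(model$fit, x, type = "response")[, , 1]
  )
  pr <- as.matrix(pr)[, lev, drop = FALSE]
  rownames(pr) <- NULL
  pr / rowSums(pr)
}

#' Predict ripeness stages
#'
#' The predicted class is the argmax of [predict_proba()], so class and
#' probability outputs always agree.
#'
#' @inheritParams predict_proba
#' @param type `"class"` for a factor of stages, `"prob"` for the
#'   probability matrix.
#' @return A factor (class) or matrix (prob).
#' @export
predict_ripeness <- function(model, data, type = c("class", "prob")) {
  type <- match.arg(type)
  pr <- predict_proba(model, data)
  if (type == "prob") return(pr)
  factor(model$levels[max.col(pr, ties.method = "first")], levels = model$levels)
}

#' Classification metrics from truth/prediction vectors
#'
#' One-vs-rest precision, recall and F1 per class plus overall accuracy,
#' computed from the confusion matrix (rows = truth, columns = predicted):
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R) (0 when P+R = 0),
#' accuracy = trace/total.
#'
#' @param truth,pred Vectors of class labels (coerced to a common factor).
#' @return A `ripeness_eval`: list with `confusion`, per-class `metrics`
#'   tibble, `accuracy` and `n`.
#' @examples
#' eval_metrics(c("a", "a", "b"), c("a", "b", "b"))$accuracy
#' @export
eval_metrics <- function(truth, pred) {
  lev <- if (is.factor(truth)) levels(truth) else sort(unique(c(as.character(truth),
                                                                as.character(pred))))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  structure(list(
    confusion = unclass(cm),
    metrics = tibble(class = lev, support = as.integer(rowSums(cm)),
                     precision = unname(prec), recall = unname(rec),
                     f1 = unname(f1)),
    accuracy = sum(tp) / sum(cm),
    n = sum(cm)
  ), class = "ripeness_eval")
}

#' Evaluate a fitted model on labelled data
#'
#' @inheritParams fit_ripeness
#' @param model A `ripeness_model`.
#' @return A `ripeness_eval` (see [eval_metrics()]).
#' @export
evaluate_ripeness <- function(model, data, label_col = "label") {
  truth <- factor(data[[label_col]], levels = model$levels)
  pred <- predict_ripeness(model, data)
  eval_metrics(truth, pred)
}

#' @export
print.ripeness_eval <- function(x, ...) {
  cat(sprintf("<ripeness_eval> accuracy %.3f on %d instances\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

stratified_folds <- function(y, k = 5, seed = 0) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified train/test split
#'
#' @param data Feature tibble with a label column.
#' @param prop Fraction of each class assigned to the training set.
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return List with `train` and `test` tibbles preserving per-class
#'   proportions.
#' @export
stratified_split <- function(data, prop = 0.7, seed = 0, label_col = "label") {
  y <- factor(data[[label_col]])
  take <- logical(nrow(data))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      take[sample(idx, round(prop * length(idx)))] <- TRUE
    }
  })
  list(train = data[take, , drop = FALSE], test = data[!take, , drop = FALSE])
}

#' Tune hyperparameters by stratified cross-validated grid search
#'
#' Stratified 5-fold cross-validation over the spec's grid (or the bundled
#' default), selecting the combination with the highest mean held-out
#' accuracy. Ties are broken toward the simpler model: fewer neighbours or
#' trees, smaller penalty C.
#'
#' @inheritParams fit_ripeness
#' @param folds Number of CV folds.
#' @return The `classifier_spec` with `params` set to the winning
#'   combination and a `cv_results` tibble (one row per grid point with its
#'   mean CV accuracy) attached.
#' @export
tune_ripeness <- function(data, spec = classifier_spec("svm"),
                          label_col = "label", seed = 0, folds = 5) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  grid <- spec$grid %||% default_grid(spec$family)
  grid_df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y <- droplevels(factor(data[[label_col]]))
  if (min(table(y)) < folds) {
    stopf("berry_too_few_samples",
          "need at least %d samples per class for %d-fold CV", folds, folds)
  }
  fold <- stratified_folds(y, k = folds, seed = seed)
  acc <- vapply(seq_len(nrow(grid_df)), function(g) {
    sp <- classifier_spec(spec$family, params = as.list(grid_df[g, , drop = FALSE]))
    mean(vapply(seq_len(folds), function(f) {
      m <- fit_ripeness(data[fold != f, , drop = FALSE], sp,
                        label_col = label_col, seed = seed)
      evaluate_ripeness(m, data[fold == f, , drop = FALSE], label_col)$accuracy
    }, numeric(1)))
  }, numeric(1))
  keys <- intersect(complexity_keys(spec$family), names(grid_df))
  ord <- do.call(order, grid_df[, keys, drop = FALSE])
  best <- ord[which(acc[ord] >= max(acc) - 1e-12)[1]]
  out <- classifier_spec(spec$family, params = as.list(grid_df[best, , drop = FALSE]),
                         grid = spec$grid)
  out$cv_results <- bind_cols(as_tibble(grid_df), tibble(mean_accuracy = acc))
  out
}

#' Per-region contribution to each ripeness stage
#'
#' Trains one classifier per single sub-region (on that region's channel
#' features only) and counts, per true stage, how many test instances each
#' region-specific model classifies correctly — revealing which part of the
#' fruit carries the signal for which stage. For a hanging berry reddening
#' from the tip up, the bottom regions separate the early stages and the top
#' regions the late ones.
#'
#' @param train,test Regional feature tibbles (columns `<channel>_<region>`)
#'   with labels.
#' @param channels Channel subset used for every fit.
#' @param spec A [classifier_spec()] (default SVM with tuned parameters).
#' @param label_col,seed As in [fit_ripeness()].
#' @return A `subregion_contribution`: list with `counts` (tibble: `stage`,
#'   `n`, then per region the number and fraction correct), `totals`
#'   (per-region overall correct counts and accuracy) and the per-region
#'   fitted accuracy.
#' @export
subregion_contribution <- function(train, test,
                                   channels = c("B", "G", "L", "a", "S"),
                                   spec = classifier_spec("svm"),
                                   label_col = "label", seed = 0) {
  channels <- check_channels(channels)
  regions <- paste0("R", 1:4)
  truth <- factor(test[[label_col]])
  per_region <- lapply(regions, function(rg) {
    cols <- paste(channels, rg, sep = "_")
    m <- fit_ripeness(train[, c(label_col, cols)], spec,
                      label_col = label_col, seed = seed)
    pred <- predict_ripeness(m, test[, cols, drop = FALSE])
    factor(as.character(pred), levels = levels(truth))
  })
  names(per_region) <- regions
  counts <- tibble(stage = levels(truth),
                   n = as.integer(table(truth)))
  for (rg in regions) {
    ok <- per_region[[rg]] == truth
    correct <- vapply(levels(truth), function(cl) sum(ok[truth == cl]), integer(1))
    counts[[paste0(rg, "_correct")]] <- unname(correct)
    counts[[paste0(rg, "_pct")]] <- unname(correct) / counts$n
  }
  totals <- tibble(
    region = regions,
    correct = unname(vapply(regions, function(rg) sum(per_region[[rg]] == truth),
                            integer(1))),
    n = length(truth)
  )
  totals$accuracy <- totals$correct / totals$n
  structure(list(counts = counts, totals = totals), class = "subregion_contribution")
}

#' @export
print.subregion_contribution <- function(x, ...) {
  cat("<subregion_contribution>\n")
  print(x$counts)
  print(x$totals)
  invisible(x)
}

#' Accuracy of region/channel subsets
#'
#' Fits one classifier per (channel, region-set) pair, using only that
#' channel's features on those regions, and reports test accuracy — the
#' ablation grid showing how much each sub-region combination contributes
#' under each colour channel.
#'
#' @inheritParams subregion_contribution
#' @param channels Channels, each evaluated on its own.
#' @param region_sets List of character vectors of regions; defaults to the
#'   four singles plus R3R4, R1R3R4, R2R3R4 and all four.
#' @return A tibble: `channel`, `regions`, `accuracy`.
#' @export
region_ablation <- function(train, test, channels = c("B", "G", "L", "a", "S"),
                            region_sets = list("R1", "R2", "R3", "R4",
                                               c("R3", "R4"), c("R1", "R3", "R4"),
                                               c("R2", "R3", "R4"),
                                               c("R1", "R2", "R3", "R4")),
                            spec = classifier_spec("svm"),
                            label_col = "label", seed = 0) {
  channels <- check_channels(channels)
  grid <- expand.grid(ch = channels, rs = seq_along(region_sets),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(ch, rs) {
    cols <- as.vector(outer(ch, region_sets[[rs]], paste, sep = "_"))
    m <- fit_ripeness(train[, c(label_col, cols)], spec,
                      label_col = label_col, seed = seed)
    tibble(channel = ch,
           regions = paste(region_sets[[rs]], collapse = ""),
           accuracy = evaluate_ripeness(m, test[, c(label_col, cols)],
                                        label_col)$accuracy)
  })
  bind_rows(rows)
}
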