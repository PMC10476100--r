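# Synthetic feature clouds on the 0-255 scale (matching the magnitude the
# default SVM gamma is calibrated for).
cloud_data <- function(n_per_class = 20, centers = list(c(40, 60), c(160, 200)),
                       sd = 5, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(centers), function(k) {
    tibble::tibble(
      f1 = rnorm(n_per_class, centers[[k]][1], sd),
      f2 = rnorm(n_per_class, centers[[k]][2], sd),
      label = paste0("class", k)
    )
  })
  df <- dplyr::bind_rows(rows)
  df$label <- factor(df$label)
  df
}

test_that("every family fits separable data and predicts it back", {
  df <- cloud_data(25, list(c(40, 60), c(160, 200), c(220, 30)))
  for (fam in c("svm", "lr", "knn", "rf")) {
    model <- fit_ripeness(df, classifier_spec(fam), seed = 0)
    ev <- evaluate_ripeness(model, df)
    expect_gte(ev$accuracy, 0.99)
  }
})

test_that("degenerate training sets and schema mismatches are rejected", {
  df <- cloud_data(10)
  single <- df[df$label == "class1", ]
  expect_error(fit_ripeness(single, classifier_spec("svm")),
               class = "berry_single_class")

  model <- fit_ripeness(df, classifier_spec("svm"), seed = 0)
  expect_error(predict_ripeness(model, tibble::tibble(f1 = 1)),
               class = "berry_schema_mismatch")
})

test_that("probabilities are normalized, consistent with predictions, deterministic", {
  df <- cloud_data(20, list(c(40, 60), c(160, 200), c(220, 30)))
  for (fam in c("svm", "lr", "knn", "rf")) {
    model <- fit_ripeness(df, classifier_spec(fam), seed = 0)
    pr <- predict_proba(model, df)
    expect_equal(rowSums(pr), rep(1, nrow(df)), tolerance = 1e-6)
    cls <- predict_ripeness(model, df)
    expect_equal(as.character(cls),
                 model$levels[apply(pr, 1, which.max)])
    # duplicated inputs get identical probability rows
    dup <- df[c(1, 1), ]
    prd <- predict_proba(model, dup)
    expect_equal(prd[1, ], prd[2, ])
  }
  # far-from-boundary point: confident probability
  model <- fit_ripeness(df, classifier_spec("svm"), seed = 0)
  far <- tibble::tibble(f1 = 40, f2 = 60)
  expect_gt(max(predict_proba(model, far)), 0.9)
})

test_that("refitting with the same seed reproduces the model exactly", {
  df <- cloud_data(20, list(c(40, 60), c(160, 200), c(100, 130)), sd = 25)
  for (fam in c("svm", "rf", "lr")) {
    m1 <- fit_ripeness(df, classifier_spec(fam), seed = 5)
    m2 <- fit_ripeness(df, classifier_spec(fam), seed = 5)
    expect_equal(predict_proba(m1, df), predict_proba(m2, df))
  }
})

test_that("evaluation metrics follow the confusion-matrix identities", {
  # perfect predictions
  ev <- eval_metrics(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  expect_equal(ev$accuracy, 1)
  expect_true(all(ev$confusion[row(ev$confusion) != col(ev$confusion)] == 0))

  # hand-computed case: per class TP = 8, FP = 2, FN = 2
  truth <- rep(c("pos", "neg"), each = 10)
  pred <- c(rep("pos", 8), rep("neg", 2), rep("neg", 8), rep("pos", 2))
  ev2 <- eval_metrics(truth, pred)
  expect_equal(ev2$metrics$precision, c(0.8, 0.8))
  expect_equal(ev2$metrics$recall, c(0.8, 0.8))
  expect_equal(ev2$metrics$f1, c(0.8, 0.8))
  expect_equal(ev2$accuracy, 0.8)

  # all wrong on a balanced two-class set
  ev3 <- eval_metrics(rep(c("a", "b"), 5), rep(c("b", "a"), 5))
  expect_equal(ev3$accuracy, 0)

  # identities on random predictions
  set.seed(77)
  for (k in 1:10) {
    tr <- sample(letters[1:4], 60, replace = TRUE)
    pd <- sample(letters[1:4], 60, replace = TRUE)
    ev <- eval_metrics(tr, pd)
    expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
    with(ev$metrics,
         expect_equal(f1, ifelse(precision + recall == 0, 0,
                                 2 * precision * recall / (precision + recall))))
    expect_equal(unname(rowSums(ev$confusion)), ev$metrics$support)
  }
})

test_that("grid search picks the best point and breaks ties toward simplicity", {
  df <- cloud_data(15, list(c(40, 60), c(160, 200)))
  # singleton grid: returns that point
  sp1 <- tune_ripeness(df, classifier_spec("svm", grid = list(C = 10, gamma = 5e-4)),
                       seed = 1)
  expect_equal(sp1$params$C, 10)
  expect_equal(sp1$params$gamma, 5e-4)
  expect_equal(nrow(sp1$cv_results), 1)
  expect_equal(max(sp1$cv_results$mean_accuracy), 1)  # separable data

  # both K values score 1.0 on separable data -> the smaller K wins
  sp2 <- tune_ripeness(df, classifier_spec("knn", grid = list(n_neighbors = c(9, 5))),
                       seed = 1)
  expect_equal(sp2$params$n_neighbors, 5)

  # determinism
  sp3 <- tune_ripeness(df, classifier_spec("knn", grid = list(n_neighbors = c(9, 5))),
                       seed = 1)
  expect_identical(sp2$cv_results, sp3$cv_results)

  tiny <- df[c(1:3, 21:23), ]
  expect_error(tune_ripeness(tiny, classifier_spec("svm")),
               class = "berry_too_few_samples")
})

test_that("stratified splitting preserves class proportions", {
  df <- cloud_data(30, list(c(40, 60), c(160, 200), c(220, 30)))
  sp <- stratified_split(df, prop = 0.7, seed = 2)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(df))
  expect_true(all(table(sp$train$label) == 21))
  expect_true(all(table(sp$test$label) == 9))
})

# Regional feature table where only chosen regions carry class signal.
region_signal_data <- function(n = 20, seed = 4, informative = "a_R1") {
  set.seed(seed)
  stages <- c("s1", "s2", "s3")
  cols <- as.vector(outer("a", paste0("R", 1:4), paste, sep = "_"))
  df <- dplyr::bind_rows(lapply(seq_along(stages), function(k) {
    out <- tibble::tibble(label = rep(stages[k], n))
    for (cl in cols) {
      mu <- if (cl %in% informative) 60 * k else 100
      out[[cl]] <- rnorm(n, mu, 4)
    }
    out
  }))
  df$label <- factor(df$label)
  df
}

test_that("sub-region contribution isolates where the signal lives", {
  df <- region_signal_data(25, informative = "a_R1")
  sp <- stratified_split(df, 0.6, seed = 1)
  contrib <- subregion_contribution(sp$train, sp$test, channels = "a", seed = 0)
  acc <- setNames(contrib$totals$accuracy, contrib$totals$region)
  expect_gt(acc[["R1"]], 0.95)              # only R1 separates the stages
  expect_lt(acc[["R4"]], 0.6)               # constant features: near chance
  # counts table is consistent
  expect_equal(sum(contrib$counts$R1_correct), contrib$totals$correct[1])
  expect_equal(sum(contrib$counts$n), nrow(sp$test))

  # combined regions never hurt relative to the best single region
  abl <- region_ablation(sp$train, sp$test, channels = "a",
                         region_sets = list("R1", "R4", paste0("R", 1:4)),
                         seed = 0)
  expect_gte(abl$accuracy[abl$regions == "R1R2R3R4"],
             max(abl$accuracy[abl$regions == "R4"]))
})

test_that("tidiers expose models and reports as tibbles", {
  df <- cloud_data(15)
  model <- fit_ripeness(df, classifier_spec("rf"), seed = 1)
  expect_named(glance(model), c("family", "n_features", "n_classes", "seed"))
  expect_equal(glance(model)$n_features, 2)
  ev <- evaluate_ripeness(model, df)
  expect_named(tidy(ev), c("class", "support", "precision", "recall", "f1"))
  expect_equal(glance(ev)$accuracy, ev$accuracy)
  expect_s3_class(autoplot(ev), "ggplot")
})
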