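# broom-style summaries of fitted objects and reports.

#' Tidy a fitted ripeness model
#'
#' @param x A `ripeness_model`.
#' @param ... Ignored.
#' @return A tibble of hyperparameters: `term`, `value`.
#' @method tidy ripeness_model
#' @export
tidy.ripeness_model <- function(x, ...) {
  tibble(term = names(x$params),
         value = vapply(x$params, function(v) as.character(v), character(1)))
}

#' @rdname tidy.ripeness_model
#' @return `glance`: one row with `family`, `n_features`, `n_classes`,
#'   `seed`.
#' @method glance ripeness_model
#' @export
glance.ripeness_model <- function(x, ...) {
  tibble(family = x$family, n_features = length(x$schema),
         n_classes = length(x$levels), seed = x$seed)
}

#' Tidy an evaluation report
#'
#' @param x A `ripeness_eval`.
#' @param ... Ignored.
#' @return Per-class metrics tibble: `class`, `support`, `precision`,
#'   `recall`, `f1`.
#' @method tidy ripeness_eval
#' @export
tidy.ripeness_eval <- function(x, ...) x$metrics

#' @rdname tidy.ripeness_eval
#' @return `glance`: one row with `accuracy`, `macro_f1`, `n`.
#' @method glance ripeness_eval
#' @export
glance.ripeness_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_f1 = mean(x$metrics$f1), n = x$n)
}

#' Tidy a tuned classifier spec
#'
#' @param x A `classifier_spec` (optionally carrying `cv_results` from
#'   [tune_ripeness()]).
#' @param ... Ignored.
#' @return The grid-search results tibble, or the current parameters if the
#'   spec was never tuned.
#' @method tidy classifier_spec
#' @export
tidy.classifier_spec <- function(x, ...) {
  x$cv_results %||%
    tibble(term = names(x$params),
           value = vapply(x$params, function(v) as.character(v), character(1)))
}

#' Tidy a sub-region contribution table
#'
#' @param x A `subregion_contribution`.
#' @param ... Ignored.
#' @return Long tibble: `stage`, `n`, `region`, `correct`, `pct`.
#' @method tidy subregion_contribution
#' @export
tidy.subregion_contribution <- function(x, ...) {
  x$counts |>
    tidyr::pivot_longer(cols = -c("stage", "n"),
                        names_to = c("region", ".value"), names_sep = "_")
}

#' Export an evaluation report
#'
#' Writes the report as JSON (accuracy plus per-class metrics) and the
#' confusion matrix as CSV.
#'
#' @param x A `ripeness_eval`.
#' @param prefix Output path prefix (`<prefix>.json`, `<prefix>_confusion.csv`).
#' @return The two paths, invisibly.
#' @export
write_eval <- function(x, prefix) {
  js <- paste0(prefix, ".json")
  cs <- paste0(prefix, "_confusion.csv")
  jsonlite::write_json(list(accuracy = x$accuracy, n = x$n,
                            per_class = x$metrics),
                       js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(data.frame(truth = rownames(x$confusion), x$confusion,
                              check.names = FALSE),
                   cs, row.names = FALSE)
  invisible(c(js, cs))
}
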